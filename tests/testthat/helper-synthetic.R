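# Shared generators for the test suite.

# Plain 2D Brownian tracks (no boundaries, no projection): the reference
# process for which the diffusion estimators are exactly calibrated.
make_brownian_tracks <- function(n_tracks, len, d_true, dt,
                                 noise_sd = 0, seed = 1, coords = "cell") {
  set.seed(seed)
  sdd <- sqrt(2 * d_true * dt)
  walk <- function() {
    steps <- matrix(stats::rnorm(n_tracks * (len - 1), 0, sdd), n_tracks)
    pos <- cbind(0, t(apply(steps, 1, cumsum)))
    if (noise_sd > 0) pos <- pos + stats::rnorm(length(pos), 0, noise_sd)
    as.vector(t(pos))
  }
  c1 <- walk()
  c2 <- walk()
  df <- data.frame(track_id = rep(seq_len(n_tracks), each = len),
                   frame = rep(0:(len - 1), n_tracks),
                   t_s = rep(0:(len - 1), n_tracks) * dt)
  if (coords == "cell") {
    df$u_um <- c1
    df$v_um <- c2
  } else {
    df$x_um <- c1
    df$y_um <- c2
  }
  as_tracks(df, coords)
}

# Minimal TrackMate-style XML: two tracks (3 + 2 spots), pixel-calibrated
# positions with pixelwidth 0.1 um and a 0.5 s frame interval.
trackmate_xml_text <- function(with_calibration = TRUE) {
  image_data <- if (with_calibration)
    '<ImageData filename="movie.tif" width="64" height="64" nslices="1" nframes="3" pixelwidth="0.1" pixelheight="0.1" voxeldepth="1.0" timeinterval="0.5"/>'
  else ""
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<TrackMate version="7.11.1">\n',
    '  <Model spatialunits="pixel" timeunits="sec">\n',
    '    <AllSpots nspots="5">\n',
    '      <SpotsInFrame frame="0">\n',
    '        <Spot ID="101" name="ID101" QUALITY="10" POSITION_X="10.0" POSITION_Y="20.0" POSITION_Z="0" POSITION_T="0" FRAME="0" RADIUS="2.5" VISIBILITY="1"/>\n',
    '        <Spot ID="104" name="ID104" QUALITY="10" POSITION_X="40.0" POSITION_Y="40.0" POSITION_Z="0" POSITION_T="0" FRAME="0" RADIUS="2.5" VISIBILITY="1"/>\n',
    '      </SpotsInFrame>\n',
    '      <SpotsInFrame frame="1">\n',
    '        <Spot ID="102" name="ID102" QUALITY="10" POSITION_X="11.0" POSITION_Y="21.0" POSITION_Z="0" POSITION_T="0.5" FRAME="1" RADIUS="2.5" VISIBILITY="1"/>\n',
    '        <Spot ID="105" name="ID105" QUALITY="10" POSITION_X="41.0" POSITION_Y="39.0" POSITION_Z="0" POSITION_T="0.5" FRAME="1" RADIUS="2.5" VISIBILITY="1"/>\n',
    '      </SpotsInFrame>\n',
    '      <SpotsInFrame frame="2">\n',
    '        <Spot ID="103" name="ID103" QUALITY="10" POSITION_X="12.0" POSITION_Y="22.0" POSITION_Z="0" POSITION_T="1.0" FRAME="2" RADIUS="2.5" VISIBILITY="1"/>\n',
    '      </SpotsInFrame>\n',
    '    </AllSpots>\n',
    '    <AllTracks>\n',
    '      <Track name="Track_0" TRACK_ID="0" NUMBER_SPOTS="3" NUMBER_GAPS="0">\n',
    '        <Edge SPOT_SOURCE_ID="101" SPOT_TARGET_ID="102" LINK_COST="1"/>\n',
    '        <Edge SPOT_SOURCE_ID="102" SPOT_TARGET_ID="103" LINK_COST="1"/>\n',
    '      </Track>\n',
    '      <Track name="Track_1" TRACK_ID="1" NUMBER_SPOTS="2" NUMBER_GAPS="0">\n',
    '        <Edge SPOT_SOURCE_ID="104" SPOT_TARGET_ID="105" LINK_COST="1"/>\n',
    '      </Track>\n',
    '    </AllTracks>\n',
    '  </Model>\n',
    '  <Settings>\n    ', image_data, '\n  </Settings>\n',
    '</TrackMate>\n')
}

write_trackmate_fixture <- function(with_calibration = TRUE) {
  path <- tempfile(fileext = ".xml")
  writeLines(trackmate_xml_text(with_calibration), path)
  path
}

# A noiseless descending staircase trace (one plateau per level).
staircase <- function(levels, plateau = 20) {
  rep(levels, each = plateau)
}
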