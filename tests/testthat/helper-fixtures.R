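# Shared fixtures, built once per test run and cached. All synthetic, all
# generated in code; sizes chosen so the whole suite runs in minutes.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

VS <- c(0.255, 0.255, 0.255)

# mid-sized islet: ~35-40 cells, several tubes
small_islet <- function() {
  fixture("small_islet", function() {
    g <- generate_capillary_network(round(c(30, 30, 30) / VS), voxel_size = VS,
                                    n_tubes = 5L, seed = 7)
    pack_cells(g, seed = 3)
  })
}

small_channels <- function() {
  fixture("small_channels", function() render_channels(small_islet(), seed = 99))
}

small_movie <- function() {
  fixture("small_movie", function() {
    simulate_fusion_movie(small_islet(), plane_z = 15, duration_s = 120,
                          seed = 11)
  })
}

# two straight parallel tubes with a gap one cell can bridge
two_tube_geometry <- function() {
  fixture("two_tube_geometry", function() {
    d <- round(c(20, 20, 20) / VS)
    labels <- array(0L, dim = d)
    ax <- function(n, dd) (seq_len(n) - 0.5) * dd
    X <- ax(d[1], VS[1]); Y <- ax(d[2], VS[2])
    r <- 2.5
    tube1 <- outer((X - 5)^2, (Y - 10)^2, "+") <= r^2
    tube2 <- outer((X - 15)^2, (Y - 10)^2, "+") <= r^2
    for (k in seq_len(d[3])) labels[, , k][tube1 | tube2] <- 1L
    labels
  })
}

# match detected events against ground truth
match_events <- function(detected, truth, max_dist = 1.5, max_frames = 2) {
  used <- rep(FALSE, nrow(detected))
  tp <- 0L; loc <- c(); dt_frames <- c()
  for (i in seq_len(nrow(truth))) {
    dd <- sqrt((detected$x_um - truth$x_um[i])^2 +
                 (detected$y_um - truth$y_um[i])^2)
    dt <- abs(detected$peak_frame - truth$peak_frame[i])
    ok <- which(!used & dd < max_dist & dt <= max_frames)
    if (length(ok) > 0) {
      j <- ok[which.min(dd[ok])]
      used[j] <- TRUE
      tp <- tp + 1L
      loc <- c(loc, dd[j]); dt_frames <- c(dt_frames, dt[j])
    }
  }
  list(recall = tp / max(nrow(truth), 1L),
       precision = tp / max(nrow(detected), 1L),
       rms_um = if (length(loc)) sqrt(mean(loc^2)) else NA_real_,
       max_frame_err = if (length(dt_frames)) max(dt_frames) else NA_real_)
}

# large validation islet (>=100 cells) shared by the acceptance checks
acceptance_islet <- function() {
  fixture("acceptance_islet", function() {
    g <- generate_capillary_network(round(c(44, 44, 44) / VS), voxel_size = VS,
                                    n_tubes = 9L, seed = 21)
    pack_cells(g, seed = 22)
  })
}

acceptance_channels <- function() {
  fixture("acceptance_channels", function() {
    g <- acceptance_islet()
    panel <- list(
      laminin = marker_spec("laminin", "capillary_surface", 8),
      dlg = marker_spec("dlg", "membrane_uniform", 4),
      liprin = marker_spec("liprin", "contact_patch", 8)
    )
    render_channels(g, panel, seed = 23)
  })
}

make_ball <- function(centre, r, box_um, vs) {
  d <- round(box_um / vs)
  ax <- function(n, dd, c0) ((seq_len(n) - 0.5) * dd - c0)^2
  R2 <- outer(outer(ax(d[1], vs[1], centre[1]), ax(d[2], vs[2], centre[2]),
                    "+"), ax(d[3], vs[3], centre[3]), "+")
  R2 <= r^2
}

make_axial_cylinder <- function(r, box_um, vs) {
  d <- round(box_um / vs)
  ax <- function(n, dd, c0) ((seq_len(n) - 0.5) * dd - c0)^2
  R2 <- outer(ax(d[1], vs[1], box_um[1] / 2), ax(d[2], vs[2], box_um[2] / 2),
              "+")
  array(rep(R2 <= r^2, d[3]), dim = d)
}

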