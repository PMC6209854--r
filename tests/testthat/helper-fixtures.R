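# Shared fixture builders; all fixtures are generated in code.

# Flood-fill connected-components oracle, written independently of the
# package's labelling: plain BFS over an adjacency generated by offsets.
oracle_label <- function(binary, connectivity = 26) {
  d <- dim(binary)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, ]
  lab <- array(0L, d)
  nextlab <- 0L
  for (v in which(binary)) {
    if (lab[v] != 0L) next
    nextlab <- nextlab + 1L
    queue <- v
    lab[v] <- nextlab
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      co <- arrayInd(u, d)
      for (r in seq_len(nrow(offs))) {
        nc <- co + as.integer(offs[r, ])
        if (any(nc < 1) || any(nc > d)) next
        w <- nc[1] + d[1] * ((nc[2] - 1) + d[2] * (nc[3] - 1))
        if (binary[w] && lab[w] == 0L) { lab[w] <- nextlab; queue <- c(queue, w) }
      }
    }
  }
  lab
}

# Brute-force TFCE oracle: double loop over discrete heights and voxels,
# relabelling from scratch at every height.
oracle_tfce <- function(z, E = 0.5, H = 2, dh = 0.05, connectivity = 26) {
  out <- array(0, dim(z))
  hmax <- max(z)
  if (hmax <= 0) return(out)
  for (k in seq_len(floor(hmax / dh + 1e-9))) {
    h <- k * dh
    lab <- oracle_label(z >= h - 1e-9, connectivity)
    sizes <- tabulate(lab)
    for (v in which(lab > 0))
      out[v] <- out[v] + sizes[lab[v]]^E * h^H * dh
  }
  out
}

# Small noise-free subject run used by several GLM tests.
noise_free_run <- function(sad = 1.5, happy = 0.5, grid = c(6, 6, 6),
                           n_volumes = 128, seed = 5) {
  td <- make_task_schedule()
  roi <- make_synthetic_roi(grid, round(grid / 2), 1)
  ns <- noise_spec(sigma_white = 0, drift_amplitude = 0, physio_amplitude = 0,
                   seed = seed)
  run <- simulate_subject_bold(td, roi, c(sad = sad, happy = happy, neutral = 0.5),
                               ns, grid, 2, n_volumes)
  list(run = run, roi = roi, design = td)
}
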