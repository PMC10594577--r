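# Shared fixtures, built in code at test time.

default_spec <- function() model_surface_spec()

# tightly converged saddle of the default model, cached per session
tight_saddle <- local({
  cache <- NULL
  function(spec = default_spec()) {
    if (is.null(cache))
      cache <<- optimize_saddle(model_energy_fn(spec), c(0.3, 0.2, -0.1),
                                threshold = 1e-9)
    cache
  }
})

default_irc <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- trace_irc(model_energy_fn(default_spec()), tight_saddle(),
                          step = 0.01)
    cache
  }
})

# minimal hand-placed trajectory: donor-hydrogen-acceptor triplet with a
# chosen donor-acceptor distance and donor-H-acceptor angle in every frame
make_hbond_traj <- function(n_frames, dist, angle_deg) {
  frames <- array(0, dim = c(3, 3, n_frames))
  # D at origin, H on x axis at 1 A; place A so that the angle at H is as
  # requested and |D - A| = dist. A lies in the xy plane.
  th <- angle_deg * pi / 180
  # direction H->D is (-1, 0, 0); rotate by the angle to get H->A direction
  dir <- c(cos(th) * -1, sin(th), 0)
  # choose |H->A| so that |D->A| = dist: solve |(1,0,0) + t*dir| = dist
  bq <- 2 * dir[1]; cq <- 1 - dist^2
  t_len <- (-bq + sqrt(bq^2 - 4 * cq)) / 2
  a_pos <- c(1, 0, 0) + t_len * dir
  for (f in seq_len(n_frames)) {
    frames[2, 1, f] <- 1
    frames[3, , f] <- a_pos
  }
  trajectory_bundle(frames, data.frame(
    name = c("DON", "HYD", "ACC"), resid = c(1L, 1L, 2L),
    resname = c("INH", "INH", "RES"),
    group = c("P1", "P1", "protein"),
    charge = 0, sigma = 0, epsilon = 0))
}
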