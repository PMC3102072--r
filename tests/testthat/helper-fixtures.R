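# Shared fixtures, computed once per test run and cached.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, maker) {
  if (!exists(name, envir = .fx_cache)) assign(name, maker(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

# Noisy oriented gratings at the four cluster orientations, one per row.
fx_oriented_patches <- function(scale, n = 400L, seed = 42L) {
  rapidscene:::with_seed(seed, {
    xs <- matrix(seq_len(scale), scale, scale, byrow = TRUE)
    ys <- matrix(seq_len(scale), scale, scale)
    t(vapply(seq_len(n), function(i) {
      th <- sample(c(0, 45, 90, 135), 1L) * pi / 180
      f <- stats::runif(1, 0.08, 0.2)
      ph <- stats::runif(1, 0, 2 * pi)
      g <- cos(2 * pi * f * (xs * sin(th) + ys * cos(th)) + ph)
      as.numeric(g * stats::runif(1, 0.5, 2) +
                   matrix(stats::rnorm(scale^2, 0, 0.05), scale, scale))
    }, numeric(scale^2)))
  })
}

fx_coarse_basis <- function() fx("coarse_basis", function()
  learn_ic_basis(fx_oriented_patches(48L, 400L, seed = 42L),
                 n_components = 16L, seed = 7L))

fx_fine_basis <- function() fx("fine_basis", function()
  learn_ic_basis(fx_oriented_patches(16L, 400L, seed = 43L),
                 n_components = 12L, seed = 8L))

# Desk-scale pipeline configuration used across inference tests and the
# acceptance protocol (chosen for runtime, fixed before the tests were run).
fx_cfg <- function() rs_config(
  n_renders = 4L, n_basis_patches = 1500L,
  n_components_coarse = 40L, n_components_fine = 30L,
  n_context = 60L, n_structures = 40L)

fx_train_ds <- function() fx("train_ds", function()
  generate_dataset(generator_config(image_size = 128L, n_positive = 10L,
                                    n_negative = 10L, separation = 1,
                                    seed = 1L)))

fx_bundle <- function() fx("bundle", function()
  suppressWarnings(train_bundle(fx_train_ds(), fx_cfg(), seed = 3L)))

# Acceptance artifacts for the separation-1 protocol: train 30+30, test 50+50.
fx_acc1 <- function() fx("acc1", function() {
  tr <- generate_dataset(generator_config(
    image_size = 128L, n_positive = 30L, n_negative = 30L,
    separation = 1, seed = 101L))
  te <- generate_dataset(generator_config(
    image_size = 128L, n_positive = 50L, n_negative = 50L,
    separation = 1, seed = 202L))
  bundle <- suppressWarnings(train_bundle(tr, fx_cfg(), seed = 11L))
  ev <- evaluate_scenes(bundle, te, seed = 12L)
  list(bundle = bundle, test = te, ev = ev)
})

# A handful of valid amplitude signature matrices for oracle tests.
fx_signatures <- function(n = 150L, seed = 5L) {
  rapidscene:::with_seed(seed, matrix(abs(stats::rnorm(n * 10L)), n, 10L))
}

# A small fitted structure pd + context model over synthetic signatures.
fx_pd_context <- function() fx("pd_context", function() {
  rapidscene:::with_seed(6L, {
    pd <- rapidscene:::new_structure_pd(
      label = rep(90L, 10L),
      samples = matrix(abs(stats::rnorm(400L, 2, 0.4)), 40L, 10L))
    recs <- tibble::tibble(
      key = c("a", "b"),
      label = list(rep(0L, 10L), rep(45L, 10L)),
      count = c(60L, 40L),
      n_objects = c(2L, 2L), sharing = c(1, 1),
      samples = list(matrix(abs(stats::rnorm(600L, 1, 0.5)), 60L, 10L),
                     matrix(abs(stats::rnorm(400L, 0.5, 0.3)), 40L, 10L)),
      mean_patch = list(NULL, NULL))
    list(pd = pd, context = build_context_model(recs, keep = 2L))
  })
})
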