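# Shared helpers: small record tables and fast sampler configurations.

tiny_juvenile_table <- function(n = 10, seed = 1) {
  set.seed(seed)
  data.frame(
    clone = rep(c("UNI", "P5"), length.out = n),
    kairomone = rep(c(TRUE, FALSE), length.out = n),
    uvr = FALSE,
    instar = 1L,
    mother_uid = make_mother_uid(rep(c("UNI", "P5"), length.out = n),
                                 rep(c(TRUE, FALSE), length.out = n), FALSE,
                                 rep(1:2, length.out = n)),
    neckteeth = sample(0:5, n, replace = TRUE),
    pedestal = sample(c("A", "B", "C"), n, replace = TRUE),
    body_length_mm = round(runif(n, 0.55, 0.8), 4),
    body_width_mm = round(runif(n, 0.3, 0.5), 4),
    spina_length_mm = round(runif(n, 0.2, 0.4), 4),
    survived_to_instar2 = TRUE,
    stringsAsFactors = FALSE)
}

fast_config <- function(seed = 1, chains = 2, iters = 400) {
  sampler_config(chains, iters, floor(iters / 2), seed = seed)
}

# posterior_draws object built from an explicit iterations x chains matrix
# replicated over the named parameters
draws_from_matrix <- function(mat, names = "theta") {
  arr <- array(rep(as.vector(mat), length(names)),
               dim = c(nrow(mat), ncol(mat), length(names)),
               dimnames = list(NULL, NULL, names))
  posterior_draws(arr, sampler_config(ncol(mat), 2 * nrow(mat), nrow(mat)))
}
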