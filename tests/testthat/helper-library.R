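# Shared fixtures built in code. The full analyte library is loaded once per
# test session; small-run simulations use a two-site subset to stay fast.

AGP_LIB <- agp_glycoform_library()
AGP_GROUPS <- attr(AGP_LIB, "groups")

lib_subset <- function(sites) {
  sub <- AGP_LIB[AGP_LIB$site_group %in% sites, ]
  class(sub) <- class(AGP_LIB)
  attr(sub, "groups") <- AGP_GROUPS
  sub
}

# deterministic two-site test rig: library subset, rt layout, simulator args
two_site_rig <- function(seed = 42, ...) {
  sub <- lib_subset(c("II_12", "V_1"))
  site_rt <- c(II_12 = 6, V_1 = 7)
  run <- simulate_run(sub, site_rt = site_rt, seed = seed, ...)
  list(lib = sub, site_rt = site_rt, run = run,
       targets = make_extraction_targets(sub, site_rt))
}

# brute-force isotope distribution by explicit polynomial expansion, one atom
# at a time (independent of the convolution-with-squaring implementation)
brute_force_pattern <- function(elements, n_iso) {
  iso <- list(
    C = c(0.9893, 0.0107), H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364), O = c(0.99757, 0.00038, 0.00205),
    S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
  )
  dist <- 1
  for (el in names(elements)) {
    for (k in seq_len(elements[[el]])) {
      p <- iso[[el]]
      new <- numeric(length(dist) + length(p) - 1)
      for (i in seq_along(dist)) {
        for (j in seq_along(p)) new[i + j - 1] <- new[i + j - 1] + dist[i] * p[j]
      }
      dist <- new
    }
  }
  dist <- dist[seq_len(min(n_iso, length(dist)))]
  dist / sum(dist)
}
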