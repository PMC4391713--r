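# Independent oracles and small fixture builders used across tests.

# Exact two-sided Mann-Whitney p by enumeration of all rank allocations:
# doubles the smaller one-sided tail of the permutation distribution of U.
enum_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  u_of <- function(idx) {
    x <- pooled[idx]
    y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  combos <- utils::combn(length(pooled), n)
  u_all <- apply(combos, 2, u_of)
  u_obs <- u_of(seq_len(n))
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Closed-form paired t on differences (hand arithmetic, no stats:: call)
closed_form_paired_t <- function(manual, automated) {
  d <- automated - manual
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  t_stat <- m / (s / sqrt(n))
  list(t = t_stat, df = n - 1, p = 2 * stats::pt(-abs(t_stat), n - 1))
}

# Minimal region-count row builder
region_row <- function(count, area = 1, sample_id = "s1", site = "sigmoid",
                       marker = "CD3", compartment = "combined",
                       method = "manual") {
  tibble::tibble(sample_id = sample_id, site = site, marker = marker,
                 compartment = compartment, area_mm2 = area, count = count,
                 method = method)
}

# Homogeneous test tissue at the study density (memoised per session so the
# heavier tests share one realisation)
homogeneous_tissue <- local({
  cache <- new.env()
  function(seed = 7) {
    key <- paste0("t", seed)
    if (is.null(cache[[key]])) {
      sim <- tissue_sim(epithelium_depth_mm = 0, aggregates_per_section = 0,
                        seed = seed)
      cache[[key]] <- generate_tissue(sim)
    }
    cache[[key]]
  }
})
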