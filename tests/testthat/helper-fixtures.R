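# Shared fixtures, built once per session and cached.
.fx <- new.env(parent = emptyenv())

fx_cached <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# small complete study used by most module tests
fx_sim <- function() {
  fx_cached("sim", function() {
    simulate_study(generator_config(n_genes = 100, module_size = 8, seed = 42))
  })
}

# probeset/gene expression derived from the small study (no lowess: the
# generator plants no array bias, so normalization is exercised separately)
fx_expr <- function() {
  fx_cached("expr", function() {
    sim <- fx_sim()
    ps <- summarize_probesets(sim$intensity, sim$models$probes)
    ge <- summarize_gene_level(ps, sim$models$probes)
    list(sim = sim, ps = ps, ge = ge)
  })
}

fx_tissue_cols <- function(design, tissue) {
  design$sample_id[design$tissue == tissue]
}

fx_log2 <- function(tbl) {
  out <- tbl
  out[-1] <- log2(tbl[-1])
  out
}

# exact rank-1 probe matrix
fx_rank1 <- function(theta = c(1, 2, 4), phi = c(1, 1, 1, 1)) {
  m <- outer(phi, theta)
  dimnames(m) <- list(paste0("p", seq_along(phi)), paste0("s", seq_along(theta)))
  m
}

# independent regex oracle for the ARE ladder (used against classify_are)
oracle_are_class <- function(seq) {
  pats <- c(
    mer13 = "[AT]{4}ATTTA[AT]{4}", mer11 = "[AT]{3}ATTTA[AT]{3}",
    mer9 = "[AT]{2}ATTTA[AT]{2}", mer7 = "[AT]ATTTA[AT]", mer5 = "ATTTA"
  )
  for (cl in names(pats)) if (grepl(pats[[cl]], seq)) return(cl)
  "none"
}

# naive per-window PWM scan oracle (string-based, substring scoring)
oracle_scan_pwm <- function(seq, pwm, min_sim) {
  L <- ncol(pwm)
  lo <- sum(apply(pwm, 2, min)); hi <- sum(apply(pwm, 2, max))
  score1 <- function(win) {
    b <- strsplit(win, "")[[1]]
    s <- 0
    for (j in seq_len(L)) {
      s <- s + if (b[j] %in% rownames(pwm)) pwm[b[j], j] else min(pwm[, j])
    }
    (s - lo) / (hi - lo)
  }
  hits <- list()
  n <- nchar(seq)
  rcseq <- revcomp(seq)
  for (o in 0:(n - L)) {
    sim_f <- score1(substr(seq, o + 1, o + L))
    if (sim_f >= min_sim) hits[[length(hits) + 1]] <-
        data.frame(offset = o, strand = "+", similarity = sim_f)
    sim_r <- score1(substr(rcseq, o + 1, o + L))
    if (sim_r >= min_sim) hits[[length(hits) + 1]] <-
        data.frame(offset = n - L - o, strand = "-", similarity = sim_r)
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) return(data.frame(offset = integer(), strand = character(),
                                      similarity = numeric()))
  out[order(out$offset, out$strand), ]
}

# brute-force GSEA running sum (independent of the package implementation)
oracle_gsea_es <- function(stats_sorted, member, weight = 1) {
  n <- length(stats_sorted)
  nh <- sum(member)
  denom_hit <- sum(abs(stats_sorted[member])^weight)
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    run <- run + if (member[i]) abs(stats_sorted[i])^weight / denom_hit else -1 / (n - nh)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}
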