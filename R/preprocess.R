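#' Lowess-normalize arrays against a median pseudo-array
#'
#' Each array's log2 intensities are compared with a reference pseudo-array
#' (the per-probe median across arrays); a locally weighted regression of the
#' log-ratio against the reference level estimates the intensity-dependent
#' bias curve, which is then subtracted. An array identical to the reference
#' is unchanged, and a second pass is idempotent up to numerical tolerance.
#'
#' @param x an `intensity_table`.
#' @param span lowess smoother span.
#' @param max_pass maximum reference/bias refinement passes; the reference
#'   moves when arrays are corrected, so the bias fit is iterated to its
#'   fixed point (this is what makes a second normalization a no-op).
#' @param tol stop when the largest absolute bias correction (log2) in a
#'   pass falls below this.
#' @return an `intensity_table` of normalized (raw-scale) intensities.
#' @export
lowess_normalize <- function(x, span = 0.3, max_pass = 2, tol = 1e-4) {
  m <- expr_matrix(x$values)
  if (ncol(m) < 2) abort("lowess normalization needs at least 2 samples")
  out <- log2(m)
  for (pass in seq_len(max_pass)) {
    ref <- apply(out, 1, median)
    biases <- vapply(seq_len(ncol(out)), function(j) {
      fit <- lowess(ref, out[, j] - ref, f = span)
      approx(fit$x, fit$y, xout = ref, rule = 2, ties = mean)$y
    }, numeric(nrow(out)))
    # center the fitted biases per probe: only array-relative bias is
    # removed, so the reference pseudo-array is left unchanged
    biases <- biases - rowMeans(biases)
    out <- out - biases
    if (max(abs(biases)) < tol) break
  }
  vals <- expr_tibble(2^out, id_col = "probe_id")
  new_intensity_table(vals, x$design)
}

#' Li-Wong (MBEI) multiplicative probe summarization
#'
#' Fits `PM_ij = theta_j * phi_i + eps_ij` for one probeset by alternating
#' least squares: update the per-sample expression index theta with the probe
#' affinities phi fixed, then phi with theta fixed, until the maximum
#' relative change in theta falls below `tol` (or `max_iter` alternations).
#' Identifiability uses `sum(phi^2) = n_probes`. After convergence, cells
#' with residuals beyond `outlier_sd` residual SDs are flagged (probes with a
#' majority of flagged cells are flagged whole) and the fit is redone once
#' with flagged cells excluded. A single-probe probeset returns that probe's
#' intensities as theta with phi = 1.
#'
#' @param probe_matrix numeric matrix (probes x samples) or wide tibble.
#' @param tol convergence tolerance on the relative change of theta.
#' @param max_iter maximum alternations per fit.
#' @param outlier_sd residual SD multiple for outlier flagging.
#' @return object of class `"liwong_fit"`: `theta` (per-sample expression
#'   index), `phi`, `outlier_cells`, `outlier_probes`, `converged`,
#'   `iterations`, `objective` (SSE trace over unflagged cells).
#' @export
liwong_summarize <- function(probe_matrix, tol = 1e-6, max_iter = 50,
                             outlier_sd = 3) {
  y <- if (is.data.frame(probe_matrix)) expr_matrix(probe_matrix) else as.matrix(probe_matrix)
  if (all(y == 0)) abort("all-zero probe matrix")
  if (ncol(y) < 2) abort("need at least 2 samples")
  p <- nrow(y)
  if (p == 1) {
    return(structure(list(
      theta = setNames(as.numeric(y[1, ]), colnames(y)), phi = 1,
      outlier_cells = matrix(FALSE, 1, ncol(y)), outlier_probes = FALSE,
      converged = TRUE, iterations = 0L, objective = 0
    ), class = "liwong_fit"))
  }
  fit1 <- liwong_als(y, w = matrix(1, p, ncol(y)), tol, max_iter)
  # Outlier cells are judged against a robust rank-1 reference (median
  # polish of log2 intensities): a least-squares fit smears a gross single
  # cell over the whole probeset, so its own residuals cannot isolate it.
  cells <- matrix(FALSE, p, ncol(y))
  if (all(y > 0)) {
    mp <- stats::medpolish(log2(y), trace.iter = FALSE)
    r <- mp$residuals
    scale <- max(1.4826 * median(abs(r)), 1e-3)
    cells <- abs(r) > outlier_sd * scale
  }
  probes <- rowMeans(cells) > 0.5
  cells[probes, ] <- TRUE
  fit <- fit1
  if (any(cells) && any(!probes)) {
    w <- matrix(1, p, ncol(y)); w[cells] <- 0
    fit <- liwong_als(y, w, tol, max_iter)
  }
  structure(list(
    theta = setNames(fit$theta, colnames(y)), phi = fit$phi,
    outlier_cells = cells, outlier_probes = probes,
    converged = fit$converged, iterations = fit$iterations,
    objective = fit$objective
  ), class = "liwong_fit")
}

# weighted rank-1 alternating least squares with sum(phi^2) = n_probes
liwong_als <- function(y, w, tol, max_iter) {
  p <- nrow(y)
  phi <- rep(1, p)
  theta <- rep(0, ncol(y))
  objective <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    theta_new <- colSums(w * phi * y) / pmax(colSums(w * phi^2), .Machine$double.eps)
    phi <- rowSums(w * y * rep(theta_new, each = p)) /
      pmax(rowSums(w * rep(theta_new^2, each = p)), .Machine$double.eps)
    sc <- sqrt(p / max(sum(phi^2), .Machine$double.eps))
    phi <- phi * sc
    theta_new <- theta_new / sc
    if (mean(theta_new) < 0) { theta_new <- -theta_new; phi <- -phi }
    objective <- c(objective, sum(w * (y - tcrossprod(phi, theta_new))^2))
    delta <- max(abs(theta_new - theta) / pmax(abs(theta_new), .Machine$double.eps))
    theta <- theta_new
    if (it > 1 && delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  list(theta = theta, phi = phi, converged = converged, iterations = it,
       objective = objective)
}

#' @export
print.liwong_fit <- function(x, ...) {
  cat(sprintf(
    "<liwong_fit> %d probes x %d samples, %s in %d iterations, %d outlier cells\n",
    length(x$phi), length(x$theta),
    if (x$converged) "converged" else "not converged",
    x$iterations, sum(x$outlier_cells)
  ))
  invisible(x)
}

#' @export
tidy.liwong_fit <- function(x, ...) {
  tibble(sample_id = names(x$theta) %||% as.character(seq_along(x$theta)),
         theta = as.numeric(x$theta))
}

#' @export
glance.liwong_fit <- function(x, ...) {
  tibble(
    n_probes = length(x$phi), n_samples = length(x$theta),
    converged = x$converged, iterations = x$iterations,
    sse = if (length(x$objective)) x$objective[length(x$objective)] else 0,
    n_outlier_cells = sum(x$outlier_cells)
  )
}

#' Summarize all probesets of an intensity table
#'
#' Runs [liwong_summarize()] per probeset and assembles the per-sample
#' expression indexes into a probeset x sample table (raw theta scale;
#' downstream analyses work on `log2(theta)`).
#'
#' @param x an `intensity_table` (normally lowess-normalized).
#' @param probe_map probe map tibble.
#' @param ... passed to [liwong_summarize()].
#' @return wide tibble: `probeset_id` + one column per sample, with a
#'   `fits` attribute (tibble of per-probeset convergence diagnostics).
#' @export
summarize_probesets <- function(x, probe_map, ...) {
  m <- expr_matrix(x$values)
  pm <- probe_map[probe_map$probe_id %in% rownames(m), ]
  split_idx <- split(match(pm$probe_id, rownames(m)), pm$probeset_id)
  fits <- vector("list", length(split_idx))
  theta <- matrix(NA_real_, length(split_idx), ncol(m),
                  dimnames = list(names(split_idx), colnames(m)))
  for (k in seq_along(split_idx)) {
    f <- liwong_summarize(m[split_idx[[k]], , drop = FALSE], ...)
    theta[k, ] <- pmax(f$theta, 2^-10)  # guard the later log2
    fits[[k]] <- glance(f)
  }
  out <- expr_tibble(theta, id_col = "probeset_id")
  attr(out, "fits") <- bind_cols(tibble(probeset_id = names(split_idx)),
                                 bind_rows(fits))
  out
}

#' Summarize probeset expression to gene level
#'
#' Applies the same multiplicative model one level up: per gene, the theta
#' vectors of its sense probesets play the probe role and a Li-Wong fit
#' yields the gene-level expression index. Antisense probesets are excluded.
#'
#' @param probeset_expr probeset x sample tibble from [summarize_probesets()].
#' @param probe_map probe map tibble (supplies probeset -> gene and region).
#' @param ... passed to [liwong_summarize()].
#' @return wide tibble: `gene_id` + one column per sample.
#' @export
summarize_gene_level <- function(probeset_expr, probe_map, ...) {
  map <- probe_map |>
    distinct(.data$probeset_id, .data$gene_id, .data$region_kind) |>
    filter(.data$region_kind != "antisense")
  m <- expr_matrix(probeset_expr)
  map <- map[map$probeset_id %in% rownames(m), ]
  genes <- split(map$probeset_id, map$gene_id)
  if (any(lengths(genes) == 0)) abort("gene with zero sense probesets")
  theta <- matrix(NA_real_, length(genes), ncol(m),
                  dimnames = list(names(genes), colnames(m)))
  for (k in seq_along(genes)) {
    sub <- m[genes[[k]], , drop = FALSE]
    if (nrow(sub) == 1) {
      theta[k, ] <- sub[1, ]
    } else {
      f <- liwong_summarize(sub, ...)
      theta[k, ] <- pmax(f$theta, 2^-10)
    }
  }
  expr_tibble(theta, id_col = "gene_id")
}

#' Flag probesets whose signal clears array background
#'
#' A probeset is effective when its log2 expression exceeds the background
#' mean plus `sd_mult` background SDs in at least `fraction` of samples,
#' where the background level is estimated per sample across the supplied
#' background probesets.
#'
#' @param probeset_expr probeset x sample tibble (theta scale).
#' @param background_ids probeset ids forming the background reference.
#' @param sd_mult SD multiple above background required.
#' @param fraction fraction of samples that must clear the threshold.
#' @return tibble: `probeset_id`, `effective`, `background_z` (mean
#'   standardized distance above background).
#' @export
detect_effective_probesets <- function(probeset_expr, background_ids,
                                       sd_mult = 2, fraction = 0.5) {
  if (length(background_ids) == 0) abort("empty background set")
  m <- log2(expr_matrix(probeset_expr))
  bg <- m[rownames(m) %in% background_ids, , drop = FALSE]
  if (nrow(bg) == 0) abort("no background probesets present in table")
  mu <- colMeans(bg)
  s <- apply(bg, 2, sd)
  s[s == 0 | is.na(s)] <- .Machine$double.eps
  above <- sweep(sweep(m, 2, mu), 2, s, "/")
  tibble(
    probeset_id = rownames(m),
    effective = rowMeans(above > sd_mult) >= fraction,
    background_z = rowMeans(above)
  )
}

#' PCA embedding of samples
#'
#' Decomposes mean-centered log2 gene expression; components are ordered by
#' decreasing variance explained.
#'
#' @param gene_expr gene x sample tibble (theta scale).
#' @param k number of components to keep.
#' @return tibble of sample coordinates (`sample_id`, `PC1..PCk`) with
#'   attribute `var_explained`.
#' @export
pca_embed <- function(gene_expr, k = 3) {
  m <- log2(expr_matrix(gene_expr))
  if (ncol(m) < 3) abort("PCA needs at least 3 samples")
  if (all(apply(m, 1, sd) == 0)) abort("constant expression matrix")
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  out <- bind_cols(tibble(sample_id = colnames(m)),
                   as_tibble(pc$x[, seq_len(k), drop = FALSE]))
  attr(out, "var_explained") <- ve
  out
}
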