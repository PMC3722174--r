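#' Read a probe-level intensity table with its sample design
#'
#' The intensity table is a TSV matrix with a `probe_id` first column and one
#' column per array; the design table maps each array to its tissue and
#' disease labels. Values are raw-scale (strictly positive) intensities.
#'
#' @param path TSV file of probe intensities (header row of sample ids).
#' @param design_path TSV file with columns `sample_id`, `tissue`, `disease`.
#' @return a list with class `"intensity_table"`: `values` (wide tibble,
#'   `probe_id` + one column per sample, ordered as in the design) and
#'   `design` (tibble).
#' @export
read_intensity_table <- function(path, design_path) {
  values <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(values)[1] <- "probe_id"
  design <- readr::read_tsv(design_path, show_col_types = FALSE, progress = FALSE)
  assert_design(design)
  if (anyDuplicated(values$probe_id)) abort("duplicate probe_id")
  samp <- sample_cols(values)
  missing <- setdiff(samp, design$sample_id)
  if (length(missing)) {
    abort(paste0("sample not in design: ", paste(missing, collapse = ", ")))
  }
  design <- design[design$sample_id %in% samp, , drop = FALSE]
  values <- values[, c("probe_id", design$sample_id)]
  m <- expr_matrix(values)
  if (anyNA(m) || !is.numeric(m)) abort("non-numeric cell in intensity table")
  if (any(m <= 0)) abort("intensities must be strictly positive (raw scale)")
  new_intensity_table(values, design)
}

new_intensity_table <- function(values, design) {
  structure(list(values = values, design = design), class = "intensity_table")
}

#' @export
print.intensity_table <- function(x, ...) {
  cat(sprintf(
    "<intensity_table> %d probes x %d samples (%s)\n",
    nrow(x$values), nrow(x$design),
    paste(sprintf(
      "%s/%s: %d", x$design$tissue, x$design$disease, 1L
    )[0], collapse = "")
  ))
  tab <- table(x$design$tissue, x$design$disease)
  print(tab)
  invisible(x)
}

#' Write an intensity table (matrix TSV + design TSV)
#'
#' @param x an `intensity_table`.
#' @param path,design_path output TSV paths.
#' @export
write_intensity_table <- function(x, path, design_path) {
  readr::write_tsv(x$values, path, progress = FALSE)
  readr::write_tsv(x$design, design_path, progress = FALSE)
  invisible(c(path, design_path))
}

#' Read gene models from GFF3 plus a probe map
#'
#' GFF3 uses 1-based inclusive coordinates; internally everything is 0-based
#' half-open (converted at this boundary). Sense probesets are attached to
#' the gene named in the probe map; antisense probesets are those declared
#' with `region_kind == "antisense"` in the probe map (the array design fixes
#' them; they are not inferred).
#'
#' @param gff_path GFF3 file with `gene`, `exon`, `five_prime_UTR`,
#'   `three_prime_UTR` features carrying `ID`/`Parent` attributes.
#' @param probemap_path TSV with columns `probe_id`, `probeset_id`,
#'   `gene_id`, `region_kind` (`five_utr`, `three_utr`, `exon`, `antisense`),
#'   `start`, `end` (0-based half-open), `strand`.
#' @return list with class `"gene_models"`: `genes` (tibble: gene_id, seqid,
#'   strand, start, end), `segments` (tibble: gene_id, kind, start, end) and
#'   `probes` (the probe map tibble).
#' @export
read_gene_models <- function(gff_path, probemap_path) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  df <- as.data.frame(gr)
  df$start0 <- df$start - 1L   # to 0-based half-open
  df$end0 <- df$end
  kinds <- c(
    gene = "gene", exon = "exon",
    five_prime_UTR = "five_utr", three_prime_UTR = "three_utr"
  )
  df <- df[as.character(df$type) %in% names(kinds), , drop = FALSE]
  genes <- df[df$type == "gene", , drop = FALSE]
  genes_tbl <- tibble(
    gene_id = as.character(genes$ID),
    seqid = as.character(genes$seqnames),
    strand = as.character(genes$strand),
    start = genes$start0, end = genes$end0
  )
  segs <- df[df$type != "gene", , drop = FALSE]
  parent <- vapply(segs$Parent, function(p) as.character(p)[1], character(1))
  segments_tbl <- tibble(
    gene_id = parent,
    kind = unname(kinds[as.character(segs$type)]),
    start = segs$start0, end = segs$end0
  )
  bad <- segments_tbl |>
    left_join(genes_tbl, by = "gene_id", suffix = c("", ".g")) |>
    filter(is.na(.data$start.g) | .data$start < .data$start.g | .data$end > .data$end.g)
  if (nrow(bad)) abort("segment outside gene span (or unknown gene)")
  probes <- read_probe_map(probemap_path)
  unknown <- setdiff(probes$gene_id, genes_tbl$gene_id)
  if (length(unknown)) {
    abort(paste0("probe mapped to absent gene: ", paste(unknown, collapse = ", ")))
  }
  new_gene_models(genes_tbl, segments_tbl, probes)
}

new_gene_models <- function(genes, segments, probes) {
  structure(
    list(genes = genes, segments = segments, probes = probes),
    class = "gene_models"
  )
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf(
    "<gene_models> %d genes, %d segments, %d probes in %d probesets\n",
    nrow(x$genes), nrow(x$segments), nrow(x$probes),
    length(unique(x$probes$probeset_id))
  ))
  invisible(x)
}

#' Read a probe map TSV
#'
#' @param path TSV path (see [read_gene_models()] for columns).
#' @return tibble, validated.
#' @export
read_probe_map <- function(path) {
  pm <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_probe_map(pm)
}

validate_probe_map <- function(pm) {
  need <- c("probe_id", "probeset_id", "gene_id", "region_kind",
            "start", "end", "strand")
  if (!all(need %in% names(pm))) {
    abort(paste0("probe map needs columns: ", paste(need, collapse = ", ")))
  }
  ok_kind <- c("five_utr", "three_utr", "exon", "antisense")
  if (!all(pm$region_kind %in% ok_kind)) abort("invalid region_kind")
  if (any(pm$start >= pm$end)) abort("probe map requires start < end")
  if (anyDuplicated(pm$probe_id)) abort("probe assigned to multiple probesets")
  n_kind <- pm |>
    distinct(.data$probeset_id, .data$region_kind) |>
    dplyr::count(.data$probeset_id)
  if (any(n_kind$n > 1)) abort("probeset with more than one region_kind")
  as_tibble(pm)
}

#' Write gene models back to GFF3 (and the probe map to TSV)
#'
#' Coordinates are converted back to 1-based inclusive GFF3 convention, so a
#' read/write round trip reproduces the original coordinates exactly.
#'
#' @param models a `gene_models` object.
#' @param gff_path,probemap_path output paths.
#' @export
write_gene_models <- function(models, gff_path, probemap_path) {
  genes <- models$genes
  segs <- models$segments |>
    left_join(genes, by = "gene_id", suffix = c("", ".gene"))
  type_of <- c(exon = "exon", five_utr = "five_prime_UTR",
               three_utr = "three_prime_UTR")
  lines <- c(
    "##gff-version 3",
    sprintf(
      "%s\texondys\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      genes$seqid, genes$start + 1L, genes$end, genes$strand, genes$gene_id
    ),
    sprintf(
      "%s\texondys\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
      segs$seqid, type_of[segs$kind], segs$start + 1L, segs$end, segs$strand,
      paste0(segs$gene_id, ":", type_of[segs$kind], ":", segs$start), segs$gene_id
    )
  )
  writeLines(lines, gff_path)
  readr::write_tsv(models$probes, probemap_path, progress = FALSE)
  invisible(gff_path)
}

#' Write a result table with a JSON sidecar
#'
#' Emits a TSV with fixed column order plus `<path>.json` holding the run
#' configuration and RNG seed so any table can be traced to the run that
#' produced it. `NaN`/`NA` p-values serialize as `NA` and restore as missing.
#'
#' @param records non-empty data frame of results.
#' @param path output TSV path.
#' @param config named list stored in the sidecar (seed included here).
#' @return the path, invisibly.
#' @export
write_result_table <- function(records, path, config = list()) {
  if (!is.data.frame(records) || nrow(records) == 0) abort("records must be non-empty")
  readr::write_tsv(records, path, na = "NA", progress = FALSE)
  sidecar <- list(
    config = config,
    columns = names(records),
    n_rows = nrow(records),
    written = "exondys"
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' @param path TSV path.
#' @return tibble (sidecar, if present, attached as attribute `"sidecar"`).
#' @export
read_result_table <- function(path) {
  out <- readr::read_tsv(path, na = "NA", show_col_types = FALSE, progress = FALSE)
  sc <- paste0(path, ".json")
  if (file.exists(sc)) attr(out, "sidecar") <- jsonlite::read_json(sc)
  out
}

#' Read / write FASTA as a named character vector
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @param seqs named character vector.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a PWM library
#'
#' Format: blocks introduced by `>tf_id`, followed by 4 tab-separated rows
#' (A, C, G, T) of per-position base probabilities or counts.
#'
#' @param path PWM library text file.
#' @param pseudocount added to every cell before column renormalization.
#' @return named list of `pwm` objects (4 x L probability matrices with
#'   rownames A,C,G,T and attribute `pseudocount`).
#' @export
read_pwm_library <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) abort("no PWM records found")
  out <- list()
  for (i in seq_along(heads)) {
    id <- sub("^>\\s*", "", lines[heads[i]])
    stop_at <- if (i < length(heads)) heads[i + 1] - 1 else length(lines)
    rows <- lines[(heads[i] + 1):stop_at]
    if (length(rows) != 4) abort(paste0("PWM ", id, " must have 4 rows (A,C,G,T)"))
    m <- do.call(rbind, lapply(rows, function(r) as.numeric(strsplit(r, "\t")[[1]])))
    out[[id]] <- new_pwm(m, id, pseudocount)
  }
  out
}

new_pwm <- function(m, tf_id, pseudocount = 0.01) {
  if (nrow(m) != 4 || ncol(m) < 4) abort("PWM must be 4 x L with L >= 4")
  rownames(m) <- c("A", "C", "G", "T")
  m <- m + pseudocount
  m <- sweep(m, 2, colSums(m), "/")
  structure(m, tf_id = tf_id, pseudocount = pseudocount, class = c("pwm", "matrix"))
}

#' @param pwms named list of PWM matrices.
#' @rdname read_pwm_library
#' @export
write_pwm_library <- function(pwms, path) {
  lines <- unlist(lapply(names(pwms), function(id) {
    m <- pwms[[id]]
    c(paste0(">", id),
      vapply(1:4, function(i) paste(format(m[i, ], digits = 10), collapse = "\t"),
             character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}
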