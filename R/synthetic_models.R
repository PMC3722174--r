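#' Generate synthetic gene models, sequences and a probe map
#'
#' Lays each gene out as 5'-UTR, two coding exons separated by one intron,
#' and a 3'-UTR (order reversed on the genomic minus strand so transcript
#' coordinates behave correctly), attaches one probeset per segment (plus an
#' antisense probeset at the 5'-UTR for genes that have one), and emits
#' promoter / intron / UTR sequences with the configured motifs planted:
#' ARE motifs of exactly the gene's class in the 3'-UTR, a TOP motif at the
#' 5'-UTR start where flagged, and exact PWM consensus sites in promoters and
#' introns of TF target genes. Sequences of non-target genes are scrubbed of
#' accidental consensus matches, and 3'-UTRs are scrubbed of accidental
#' AUUUA cores before planting, so the planted truth is exact.
#'
#' @param config a [generator_config()].
#' @param effects effect table from [simulate_effects()] (defaults to
#'   drawing it from `config`, which keeps the two consistent).
#' @return list with `models` (a `gene_models` object), `sequences` (named
#'   character vector, names `<gene>|promoter` / `|intron` / `|five_utr` /
#'   `|three_utr`), `pwms` (named list of PWM matrices) and `effects`.
#' @export
generate_gene_models <- function(config, effects = simulate_effects(config)) {
  cfg <- config
  set.seed(stage_seed(cfg$seed, "models") + 1L)
  n <- cfg$n_genes
  stopifnot(nrow(effects) == n)
  t1 <- cfg$tissues[1]

  seg_lens <- c(five_utr = cfg$utr5_len, exon1 = cfg$exon_len,
                intron1 = cfg$intron_len, exon2 = cfg$exon_len,
                three_utr = cfg$utr3_len)
  gene_len <- sum(seg_lens)
  gap <- 1000L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gstart <- (seq_len(n) - 1L) * (gene_len + gap) + cfg$promoter_len

  genes_tbl <- tibble(
    gene_id = effects$gene_id, seqid = "chr1", strand = strand,
    start = gstart, end = gstart + gene_len
  )

  seg_rows <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- if (strand[i] == "+") names(seg_lens) else rev(names(seg_lens))
    starts <- gstart[i] + cumsum(c(0L, unname(seg_lens[ord])[-length(seg_lens)]))
    seg_rows[[i]] <- tibble(
      gene_id = effects$gene_id[i],
      seg = ord,
      kind = sub("[0-9]$", "", ord),
      start = starts, end = starts + unname(seg_lens[ord])
    )
  }
  segments_all <- bind_rows(seg_rows)
  segments_tbl <- segments_all |>
    filter(.data$kind != "intron") |>
    select("gene_id", "kind", "start", "end")

  # --- probe map -----------------------------------------------------------
  probe_len <- 25L
  probes_for <- function(gene, seg, kind, a, b, k, strand, suffix = NULL) {
    ps <- paste0(gene, ":", suffix %||% seg)
    if (k == 1) starts <- as.integer(a + (b - a - probe_len) %/% 2)
    else starts <- as.integer(a + floor((b - a - probe_len) * (seq_len(k) - 1) / (k - 1)))
    tibble(
      probe_id = paste0(ps, "_p", seq_len(k)), probeset_id = ps,
      gene_id = gene, region_kind = kind,
      start = starts, end = starts + probe_len, strand = strand
    )
  }
  pm_rows <- vector("list", n)
  for (i in seq_len(n)) {
    segs <- seg_rows[[i]]
    g <- effects$gene_id[i]
    rows <- lapply(seq_len(nrow(segs)), function(j) {
      if (segs$kind[j] == "intron") return(NULL)
      k <- if (segs$kind[j] == "three_utr") cfg$three_utr_probes else cfg$probes_per_probeset
      probes_for(g, segs$seg[j], segs$kind[j], segs$start[j], segs$end[j], k, strand[i])
    })
    if (effects$antisense_mode[i] != "none") {
      five <- segs[segs$seg == "five_utr", ]
      rows <- c(rows, list(probes_for(
        g, "anti", "antisense", five$start, five$end,
        cfg$probes_per_probeset, if (strand[i] == "+") "-" else "+", "anti"
      )))
    }
    pm_rows[[i]] <- bind_rows(rows)
  }
  # dedicated background-reference probesets (antisense strand, spread over genes)
  if (cfg$n_background_reference > 0) {
    host <- rep_len(seq_len(n), cfg$n_background_reference)
    bg_rows <- lapply(seq_len(cfg$n_background_reference), function(j) {
      i <- host[j]
      segs <- seg_rows[[i]]
      ex <- segs[segs$seg == "exon1", ]
      probes_for(effects$gene_id[i], paste0("bgref", j), "antisense",
                 ex$start, ex$end, cfg$probes_per_probeset,
                 if (strand[i] == "+") "-" else "+", paste0("bgref", j))
    })
    pm_rows <- c(pm_rows, bg_rows)
  }
  probe_map <- validate_probe_map(bind_rows(pm_rows))

  # --- PWM library ---------------------------------------------------------
  pwms <- simulate_pwm_library(cfg)

  # --- sequences -----------------------------------------------------------
  seqs <- character(0)
  rand_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  are_insert <- c(
    mer5 = "CATTTAC", mer7 = "CTATTTATC", mer9 = "CTTATTTATTC",
    mer11 = "CTTTATTTATTTC", mer13 = "CTTTTATTTATTTTC"
  )
  consensus <- vapply(pwms, pwm_consensus, character(1))
  consensus_rc <- vapply(consensus, revcomp, character(1))
  slot_at <- setNames(50L + 60L * (seq_along(pwms) - 1L), names(pwms))

  plant <- function(seq, insert, at) {
    paste0(substr(seq, 1, at - 1), insert,
           substr(seq, at + nchar(insert), nchar(seq)))
  }
  scrub_all_tf <- function(seq, tfs_keep) {
    for (tf in names(pwms)) {
      if (tf %in% tfs_keep) next
      for (pat in c(consensus[[tf]], consensus_rc[[tf]])) {
        seq <- scrub_motif(seq, pat)
      }
    }
    seq
  }

  for (i in seq_len(n)) {
    g <- effects$gene_id[i]
    prom <- scrub_all_tf(rand_dna(cfg$promoter_len), effects$tf_promoter[[i]])
    for (tf in effects$tf_promoter[[i]]) {
      prom <- plant(prom, consensus[[tf]], slot_at[[tf]])
    }
    intr <- scrub_all_tf(rand_dna(cfg$intron_len), effects$tf_intron[[i]])
    for (tf in effects$tf_intron[[i]]) {
      intr <- plant(intr, consensus[[tf]], min(slot_at[[tf]], cfg$intron_len - 20L))
    }
    utr5 <- rand_dna(cfg$utr5_len)
    if (effects$top_motif[i]) {
      utr5 <- paste0("CTTTTT", substr(utr5, 7, nchar(utr5)))
    } else {
      utr5 <- paste0(sample(c("A", "G"), 1), substr(utr5, 2, nchar(utr5)))
    }
    utr3 <- scrub_motif(rand_dna(cfg$utr3_len), "ATTTA")
    cls <- effects$are_class[i]
    if (cls != "none") {
      ins <- are_insert[[cls]]
      at <- sample.int(cfg$utr3_len - nchar(ins) - 10L, 1) + 5L
      utr3 <- plant(utr3, ins, at)
    }
    seqs[paste0(g, "|promoter")] <- prom
    seqs[paste0(g, "|intron")] <- intr
    seqs[paste0(g, "|five_utr")] <- utr5
    seqs[paste0(g, "|three_utr")] <- utr3
  }

  list(
    models = new_gene_models(genes_tbl, segments_tbl, probe_map),
    sequences = seqs,
    pwms = pwms,
    effects = effects
  )
}

#' Simulate a PWM library
#'
#' One 15-bp PPRE-like matrix and one 8-bp TATA-like matrix are always
#' included, plus `n_tfs` generic motifs. Each PWM places probability 0.85 on
#' a random consensus base and 0.05 elsewhere, so a 95%-similarity match
#' requires the exact consensus.
#'
#' @param config a [generator_config()].
#' @return named list of PWM matrices.
#' @export
simulate_pwm_library <- function(config) {
  lens <- c(PPRE = 15L, TATA = 8L)
  if (config$n_tfs > 0) {
    extra <- setNames(rep(config$tf_motif_length, config$n_tfs),
                      sprintf("TF%02d", seq_len(config$n_tfs)))
    lens <- c(lens, extra)
  }
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (id in names(lens)) {
    cons <- sample(bases, lens[[id]], replace = TRUE)
    m <- matrix(0.05, nrow = 4, ncol = lens[[id]], dimnames = list(bases, NULL))
    for (j in seq_along(cons)) m[cons[j], j] <- 0.85
    out[[id]] <- new_pwm(m, id, pseudocount = 0.01)
  }
  out
}

#' Consensus string of a PWM (highest-probability base per column)
#' @param pwm a PWM matrix.
#' @return character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm)[apply(pwm, 2, which.max)], collapse = "")
}

#' Reverse complement of a DNA string
#' @param x character scalar over A,C,G,T,N.
#' @return character scalar.
#' @export
revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]), collapse = "")
}

# Remove every occurrence of `motif` from `seq` by mutating its middle base.
scrub_motif <- function(seq, motif, to = "G") {
  mid <- nchar(motif) %/% 2 + 1L
  alt <- if (substr(motif, mid, mid) == to) "C" else to
  repeat {
    at <- regexpr(motif, seq, fixed = TRUE)
    if (at < 0) break
    substr(seq, at + mid - 1L, at + mid - 1L) <- alt
  }
  seq
}
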