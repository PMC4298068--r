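#' Configuration for the splicing-data simulator
#'
#' Defines the generative model used by [simulate_splicing_dataset()]. The
#' simulator emulates the structure the regression model assumes: per gene
#' a class-dependent expression baseline with per-sample noise; per exon a
#' linear response to the gene signal with its own slope and intercept
#' (standing in for the accumulated response of its probes); per probe an
#' additive affinity offset plus measurement noise; and, for a chosen
#' fraction of exons, a class-specific additive log2 offset -- the injected
#' splicing event.
#'
#' @param n_genes number of gene loci.
#' @param exons_per_gene integer range (min, max) of exons per gene.
#' @param n_classes number of sample classes (tissues, subtypes, ...).
#' @param replicates_per_class samples per class.
#' @param probes_per_exon integer range of probes per exon.
#' @param baseline_range range of per-gene mean log2 expression.
#' @param class_sd sd of the per-gene, per-class baseline shift (log2);
#'   together with `gene_noise_sd` this guarantees spread in the gene
#'   signal, which the regression needs.
#' @param gene_noise_sd sd of per-sample noise on the gene signal (log2).
#' @param slope_mean,slope_sd distribution of exon slopes (centered at 1:
#'   an unspliced exon tracks its gene).
#' @param intercept_sd sd of exon intercepts (probe-affinity offsets, log2).
#' @param probe_effect_sd sd of per-probe additive affinity effects (log2).
#' @param probe_noise_sd sd of per-probe measurement noise (log2).
#' @param noise_sd sd of exon-level residual noise (log2).
#' @param splicing_fraction fraction of exons carrying an injected
#'   splicing event, in `[0, 1]`.
#' @param effect_size absolute size of the injected class-specific offset
#'   (log2); the sign is drawn at random per event.
#' @param ambiguous_fraction fraction of probes flagged ambiguous (to
#'   exercise the exclusion rule).
#' @param seed mandatory random seed (reproducibility is part of the
#'   contract).
#' @return a validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 200L,
                              exons_per_gene = c(4L, 10L),
                              n_classes = 3L,
                              replicates_per_class = 10L,
                              probes_per_exon = c(3L, 5L),
                              baseline_range = c(6, 12),
                              class_sd = 1,
                              gene_noise_sd = 0.5,
                              slope_mean = 1,
                              slope_sd = 0.2,
                              intercept_sd = 0.5,
                              probe_effect_sd = 0.3,
                              probe_noise_sd = 0.1,
                              noise_sd = 0.25,
                              splicing_fraction = 0.05,
                              effect_size = 1.0,
                              ambiguous_fraction = 0,
                              seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory for reproducible simulation")
  cfg <- list(n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              n_classes = as.integer(n_classes),
              replicates_per_class = as.integer(replicates_per_class),
              probes_per_exon = as.integer(probes_per_exon),
              baseline_range = as.numeric(baseline_range),
              class_sd = as.numeric(class_sd),
              gene_noise_sd = as.numeric(gene_noise_sd),
              slope_mean = as.numeric(slope_mean),
              slope_sd = as.numeric(slope_sd),
              intercept_sd = as.numeric(intercept_sd),
              probe_effect_sd = as.numeric(probe_effect_sd),
              probe_noise_sd = as.numeric(probe_noise_sd),
              noise_sd = as.numeric(noise_sd),
              splicing_fraction = as.numeric(splicing_fraction),
              effect_size = as.numeric(effect_size),
              ambiguous_fraction = as.numeric(ambiguous_fraction),
              seed = as.integer(seed))
  bad <- character()
  if (cfg$n_genes < 1L) bad <- c(bad, "n_genes")
  if (length(cfg$exons_per_gene) != 2L || any(cfg$exons_per_gene < 1L) ||
      diff(cfg$exons_per_gene) < 0) bad <- c(bad, "exons_per_gene")
  if (cfg$n_classes < 2L) bad <- c(bad, "n_classes")
  if (cfg$replicates_per_class < 2L) bad <- c(bad, "replicates_per_class")
  if (length(cfg$probes_per_exon) != 2L || any(cfg$probes_per_exon < 1L) ||
      diff(cfg$probes_per_exon) < 0) bad <- c(bad, "probes_per_exon")
  sds <- c("class_sd", "gene_noise_sd", "slope_sd", "intercept_sd",
           "probe_effect_sd", "probe_noise_sd", "noise_sd")
  for (s in sds) if (cfg[[s]] < 0) bad <- c(bad, s)
  if (cfg$splicing_fraction < 0 || cfg$splicing_fraction > 1)
    bad <- c(bad, "splicing_fraction")
  if (cfg$ambiguous_fraction < 0 || cfg$ambiguous_fraction > 1)
    bad <- c(bad, "ambiguous_fraction")
  if (length(bad))
    stop("invalid simulation config field(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "simulation_config")
}

#' Simulate an exon-expression dataset with known splicing ground truth
#'
#' Generates gene models, a probe-to-exon mapping, a probe-level log2
#' expression matrix, sample class labels, and a truth table of injected
#' splicing events, so every stage of the pipeline can be exercised and
#' scored without external data. Exon- and gene-level matrices (the true
#' underlying signals, before the probe layer) are also returned so the
#' regression stage can be tested in isolation from summarization.
#'
#' Generative model, all on the log2 scale: gene signal
#' `g_jk = mu_j + delta_{j,class(k)} + N(0, gene_noise_sd)`; exon signal
#' `e_ijk = b_ij + s_ij * g_jk + Delta * [event(i, j, class(k))] +
#' N(0, noise_sd)`; probe signal `e_ijk + probe_effect + N(0,
#' probe_noise_sd)`. Each gene model carries one full-length transcript and
#' one short 5' transcript (below the default coverage threshold), so core
#' selection keeps every exon.
#'
#' @param cfg a [simulation_config()].
#' @return list with `models`, `mapping`, `probe_matrix`, `exon_matrix`
#'   (with `gene_id` attribute), `gene_matrix`, `exon_genes`, `classes`,
#'   `truth` (data.frame `gene_id`, `exon_id`, `class`, `delta`), and
#'   `params` (true slopes/intercepts per exon).
#' @export
simulate_splicing_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)

  n_samples <- cfg$n_classes * cfg$replicates_per_class
  class_names <- paste0("class", seq_len(cfg$n_classes))
  classes <- factor(rep(class_names, each = cfg$replicates_per_class),
                    levels = class_names)
  sample_ids <- paste0(rep(class_names, each = cfg$replicates_per_class),
                       "_s", rep(seq_len(cfg$replicates_per_class),
                                 cfg$n_classes))
  names(classes) <- sample_ids

  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  n_ex <- sample(seq(cfg$exons_per_gene[1L], cfg$exons_per_gene[2L]),
                 cfg$n_genes, replace = TRUE)
  exon_ids <- unlist(lapply(seq_len(cfg$n_genes), function(j)
    sprintf("%s_E%02d", gene_ids[j], seq_len(n_ex[j]))))
  exon_genes <- stats::setNames(rep(gene_ids, n_ex), exon_ids)
  n_exons <- length(exon_ids)

  # gene models: exons laid out on one chromosome per gene; one transcript
  # spanning the locus plus one short 5' transcript
  models <- lapply(seq_len(cfg$n_genes), function(j) {
    k <- n_ex[j]
    starts <- (seq_len(k) - 1L) * 500L + 1L
    ex <- data.frame(exon_id = sprintf("%s_E%02d", gene_ids[j], seq_len(k)),
                     chrom = paste0("chr", j), start = starts,
                     end = starts + 149L, strand = "+",
                     stringsAsFactors = FALSE)
    txs <- list(full = ex$exon_id)
    bios <- c(full = "protein_coding")
    if (k >= 3L) {
      txs$short <- ex$exon_id[seq_len(max(1L, floor(k / 3)))]
      bios <- c(bios, short = "processed_transcript")
    }
    names(txs) <- paste0(gene_ids[j], "_T", seq_along(txs))
    names(bios) <- names(txs)
    new_gene_model(gene_ids[j], ex, txs, bios)
  })
  names(models) <- gene_ids

  # gene signal
  mu <- stats::runif(cfg$n_genes, cfg$baseline_range[1L],
                     cfg$baseline_range[2L])
  class_shift <- matrix(stats::rnorm(cfg$n_genes * cfg$n_classes,
                                     sd = cfg$class_sd),
                        nrow = cfg$n_genes,
                        dimnames = list(gene_ids, class_names))
  gene_matrix <- mu + class_shift[, as.character(classes), drop = FALSE] +
    matrix(stats::rnorm(cfg$n_genes * n_samples, sd = cfg$gene_noise_sd),
           nrow = cfg$n_genes)
  dimnames(gene_matrix) <- list(gene_ids, sample_ids)

  # injected splicing events: (gene, exon, class) additive offsets
  n_events <- floor(cfg$splicing_fraction * n_exons)
  if (n_events > 0L) {
    ev_exons <- sample(exon_ids, n_events)
    ev_class <- sample(class_names, n_events, replace = TRUE)
    ev_delta <- sample(c(-1, 1), n_events, replace = TRUE) * cfg$effect_size
    truth <- data.frame(gene_id = unname(exon_genes[ev_exons]),
                        exon_id = ev_exons, class = ev_class,
                        delta = ev_delta, stringsAsFactors = FALSE)
  } else {
    truth <- data.frame(gene_id = character(), exon_id = character(),
                        class = character(), delta = numeric(),
                        stringsAsFactors = FALSE)
  }

  # exon signal
  slopes <- stats::setNames(stats::rnorm(n_exons, cfg$slope_mean,
                                         cfg$slope_sd), exon_ids)
  intercepts <- stats::setNames(stats::rnorm(n_exons, 0, cfg$intercept_sd),
                                exon_ids)
  exon_matrix <- intercepts + slopes *
    gene_matrix[exon_genes, , drop = FALSE] +
    matrix(stats::rnorm(n_exons * n_samples, sd = cfg$noise_sd),
           nrow = n_exons)
  dimnames(exon_matrix) <- list(exon_ids, sample_ids)
  if (nrow(truth)) {
    for (i in seq_len(nrow(truth))) {
      cols <- classes == truth$class[i]
      exon_matrix[truth$exon_id[i], cols] <-
        exon_matrix[truth$exon_id[i], cols] + truth$delta[i]
    }
  }
  attr(exon_matrix, "gene_id") <- exon_genes

  # probe layer
  n_probes <- sample(seq(cfg$probes_per_exon[1L], cfg$probes_per_exon[2L]),
                     n_exons, replace = TRUE)
  probe_exon <- rep(exon_ids, n_probes)
  probe_ids <- paste0(probe_exon, "_P",
                      unlist(lapply(n_probes, seq_len)))
  probe_effects <- stats::rnorm(length(probe_ids), 0, cfg$probe_effect_sd)
  probe_matrix <- exon_matrix[probe_exon, , drop = FALSE] + probe_effects +
    matrix(stats::rnorm(length(probe_ids) * n_samples,
                        sd = cfg$probe_noise_sd),
           nrow = length(probe_ids))
  dimnames(probe_matrix) <- list(probe_ids, sample_ids)
  attr(probe_matrix, "gene_id") <- NULL

  mapping <- data.frame(probe_id = probe_ids,
                        gene_id = unname(exon_genes[probe_exon]),
                        exon_id = probe_exon,
                        ambiguous = stats::runif(length(probe_ids)) <
                          cfg$ambiguous_fraction,
                        stringsAsFactors = FALSE)

  list(models = models, mapping = mapping, probe_matrix = probe_matrix,
       exon_matrix = exon_matrix, gene_matrix = gene_matrix,
       exon_genes = exon_genes, classes = classes, truth = truth,
       params = list(slope = slopes, intercept = intercepts),
       config = cfg)
}

#' Deterministic multi-transcript gene-model fixture
#'
#' A fixed 15-exon, 6-transcript gene model reproducing the locus
#' architecture of the human regucalcin (RGN) gene on chromosome X, the
#' canonical illustration of why gene-signal definitions matter: two short
#' "processed transcript" isoforms span under 60% of the locus, the four
#' long protein-coding transcripts share exactly 5 common exons, and no
#' exon is present in all six transcripts. Consequently core selection at
#' the 0.60 coverage threshold returns 5 exons, selection over all
#' transcripts returns none (gene signal not measurable), and the full
#' locus has 15 exons. Exon coordinates are schematic; the
#' exon-by-transcript membership is the contract.
#'
#' The same model ships as a TSV at
#' `system.file("extdata", "rgn_architecture.tsv", package = "eslim")`.
#'
#' @return list with `model` (a `gene_model`) and `coverage` (data.frame of
#'   per-transcript locus coverage and biotype).
#' @examples
#' fx <- rgn_fixture()
#' select_core_exons(fx$model, "core", 0.60)
#' @export
rgn_fixture <- function() {
  starts <- (seq_len(15L) - 1L) * 700L + 1L
  exons <- data.frame(exon_id = sprintf("E%02d", seq_len(15L)),
                      chrom = "chrX", start = starts, end = starts + 99L,
                      strand = "-", stringsAsFactors = FALSE)
  txs <- list(
    `RGN-001` = sprintf("E%02d", c(1, 2, 4, 5, 6, 8, 10, 11, 12, 13, 15)),
    `RGN-002` = sprintf("E%02d", c(2, 4, 6, 7, 8, 10, 12, 14)),
    `RGN-201` = sprintf("E%02d", c(3, 4, 5, 6, 8, 9, 10, 12, 13)),
    `RGN-202` = sprintf("E%02d", c(1, 4, 6, 8, 10, 12, 15)),
    `RGN-003` = sprintf("E%02d", c(1, 2, 3)),
    `RGN-004` = sprintf("E%02d", c(13, 14, 15)))
  bios <- c(`RGN-001` = "protein_coding", `RGN-002` = "protein_coding",
            `RGN-201` = "protein_coding", `RGN-202` = "protein_coding",
            `RGN-003` = "processed_transcript",
            `RGN-004` = "processed_transcript")
  model <- new_gene_model("RGN", exons, txs, bios)
  coverage <- data.frame(
    transcript_id = names(txs),
    biotype = unname(bios),
    coverage = vapply(names(txs), function(tx)
      transcript_coverage(model, tx), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(coverage) <- NULL
  list(model = model, coverage = coverage)
}
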