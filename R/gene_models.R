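#' Gene models: loci, transcripts, exons
#'
#' A gene model describes one gene locus: the set of distinct exons it
#' contains and the transcripts (ordered sets of exon ids) expressed from it.
#' Gene models drive the selection of the exons used to compute the
#' whole-gene expression signal (see [select_core_exons()]).
#'
#' @name gene_models
NULL

.valid_strands <- c("+", "-")

new_gene_model <- function(gene_id, exons, transcripts, biotypes) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  stopifnot(is.data.frame(exons),
            all(c("exon_id", "chrom", "start", "end", "strand") %in%
                  names(exons)))
  if (anyDuplicated(exons$exon_id))
    stop("duplicated exon_id within locus ", gene_id)
  if (any(exons$start > exons$end))
    stop("exon with start > end in locus ", gene_id)
  if (length(transcripts) == 0L)
    stop("gene model ", gene_id, " has no transcripts")
  for (tx in names(transcripts)) {
    missing_ex <- setdiff(transcripts[[tx]], exons$exon_id)
    if (length(missing_ex))
      stop("transcript ", tx, " references unknown exon(s): ",
           paste(missing_ex, collapse = ", "))
    if (length(transcripts[[tx]]) == 0L)
      stop("transcript ", tx, " has no exons")
  }
  structure(
    list(gene_id = gene_id,
         exons = exons[order(exons$start, exons$end), , drop = FALSE],
         transcripts = transcripts,
         biotypes = biotypes,
         locus_span = c(start = min(exons$start), end = max(exons$end))),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("Gene model", x$gene_id, "\n")
  cat("  locus span:", x$exons$chrom[1L], x$locus_span["start"], "-",
      x$locus_span["end"],
      sprintf("(%d bp)\n", x$locus_span["end"] - x$locus_span["start"] + 1L))
  cat(" ", nrow(x$exons), "exons,", length(x$transcripts), "transcripts\n")
  for (tx in names(x$transcripts)) {
    cat(sprintf("  %-12s %-20s %2d exons, coverage %.2f\n", tx,
                x$biotypes[[tx]], length(x$transcripts[[tx]]),
                transcript_coverage(x, tx)))
  }
  invisible(x)
}

#' Load gene models from an annotation file
#'
#' Reads either a tab-separated transcript-exon table or a GTF/GFF file and
#' builds one [gene model][gene_models] per gene. The TSV format has one row
#' per (transcript, exon) membership with columns `gene_id`, `transcript_id`,
#' `exon_id`, `chrom`, `start`, `end`, `strand` and optionally `biotype`
#' (e.g. `protein_coding`, `processed_transcript`). Coordinates are 1-based
#' inclusive (GTF convention).
#'
#' Exons that share identical `(chrom, start, end, strand)` within a locus
#' are merged into a single exon record shared by the transcripts that carry
#' them; loading is therefore idempotent.
#'
#' @param path path to a `.tsv`/`.txt` table or a `.gtf`/`.gff` file, or a
#'   data.frame in the TSV layout.
#' @return a named list of `gene_model` objects, one per `gene_id`.
#' @export
load_gene_models <- function(path) {
  if (is.data.frame(path)) {
    tab <- path
  } else if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE)) {
    tab <- .read_gtf_exons(path)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  if (nrow(tab) == 0L) return(structure(list(), names = character()))
  req <- c("gene_id", "transcript_id", "exon_id", "chrom", "start", "end",
           "strand")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("annotation table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!("biotype" %in% names(tab))) tab$biotype <- NA_character_
  tab$start <- suppressWarnings(as.integer(tab$start))
  tab$end <- suppressWarnings(as.integer(tab$end))
  bad <- which(is.na(tab$start) | is.na(tab$end) | tab$start > tab$end |
                 !(tab$strand %in% .valid_strands) | is.na(tab$gene_id) |
                 tab$gene_id == "" | is.na(tab$transcript_id) |
                 tab$transcript_id == "")
  if (length(bad))
    stop("malformed annotation row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))

  models <- lapply(split(tab, tab$gene_id), function(g) {
    # merge exons identical in coordinates; first exon_id seen wins
    key <- paste(g$chrom, g$start, g$end, g$strand, sep = ":")
    canon <- tapply(g$exon_id, key, function(ids) sort(ids)[1L])
    g$exon_id <- unname(canon[key])
    ex <- unique(g[, c("exon_id", "chrom", "start", "end", "strand")])
    rownames(ex) <- NULL
    txs <- lapply(split(g, g$transcript_id),
                  function(t) unique(t$exon_id[order(t$start)]))
    bios <- vapply(split(g, g$transcript_id),
                   function(t) t$biotype[1L], character(1))
    new_gene_model(g$gene_id[1L], ex, txs, bios)
  })
  models[order(names(models))]
}

.read_gtf_exons <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GTF/GFF requires the rtracklayer package; ",
         "alternatively provide the annotation as a TSV table")
  gr <- rtracklayer::import(path)
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  md <- as.data.frame(gr)
  bio <- md$transcript_biotype
  if (is.null(bio)) bio <- md$gene_biotype
  if (is.null(bio)) bio <- NA_character_
  exid <- md$exon_id
  if (is.null(exid))
    exid <- paste0(md$seqnames, ":", md$start, "-", md$end, ":", md$strand)
  data.frame(gene_id = md$gene_id, transcript_id = md$transcript_id,
             exon_id = exid, chrom = as.character(md$seqnames),
             start = md$start, end = md$end,
             strand = as.character(md$strand), biotype = bio,
             stringsAsFactors = FALSE)
}

#' Fraction of the gene locus covered by a transcript
#'
#' Coverage of the locus by a transcript, used by the gene-core rule: short
#' transcripts covering less than the threshold (default 60%) of the locus
#' are ignored when defining the consensus exon set. By default coverage is
#' the transcript's genomic span (first exon start to last exon end) divided
#' by the locus span; `metric = "exonic"` instead uses summed exonic length
#' relative to the merged exonic length of the locus.
#'
#' @param model a `gene_model`.
#' @param transcript_id a transcript of that model.
#' @param metric `"span"` (default) or `"exonic"`.
#' @return a fraction in (0, 1].
#' @export
transcript_coverage <- function(model, transcript_id,
                                metric = c("span", "exonic")) {
  stopifnot(inherits(model, "gene_model"))
  metric <- match.arg(metric)
  if (!transcript_id %in% names(model$transcripts))
    stop("transcript ", transcript_id, " not in gene ", model$gene_id)
  ex <- model$exons
  tex <- ex[ex$exon_id %in% model$transcripts[[transcript_id]], , drop = FALSE]
  if (metric == "span") {
    tspan <- max(tex$end) - min(tex$start) + 1
    lspan <- model$locus_span["end"] - model$locus_span["start"] + 1
    unname(tspan / lspan)
  } else {
    sum(.merged_length(tex)) / sum(.merged_length(ex))
  }
}

# total length of the union of a set of intervals
.merged_length <- function(ex) {
  o <- order(ex$start, ex$end)
  s <- ex$start[o]; e <- ex$end[o]
  tot <- 0; cur_s <- s[1L]; cur_e <- e[1L]
  for (i in seq_along(s)[-1L]) {
    if (s[i] <= cur_e + 1L) cur_e <- max(cur_e, e[i])
    else { tot <- tot + (cur_e - cur_s + 1L); cur_s <- s[i]; cur_e <- e[i] }
  }
  tot + (cur_e - cur_s + 1L)
}

#' Select the exons defining a gene's expression signal
#'
#' Implements the three gene-signal definitions compared by the method:
#' \describe{
#'   \item{`all`}{every exon of the locus (the conventional default, blind
#'     to locus architecture).}
#'   \item{`total`}{only exons present in every known transcript of the
#'     locus; stringent, and empty for many loci (the gene signal is then
#'     not measurable).}
#'   \item{`core`}{the "gene core": exons present in every transcript whose
#'     locus coverage is at least `threshold` (default 0.60). Short
#'     transcripts -- frequently unstable "processed transcript"
#'     annotations -- are thereby ignored.}
#' }
#'
#' If, in `core` mode, no transcript reaches the coverage threshold, the
#' single transcript with maximal coverage is used instead (with a warning)
#' so that the gene is not silently lost.
#'
#' @param model a `gene_model` (or a list of them, in which case a named
#'   list of selections is returned).
#' @param mode `"core"`, `"total"` or `"all"`.
#' @param threshold minimum locus coverage for a transcript to count in
#'   `core` mode, in (0, 1].
#' @param metric coverage metric passed to [transcript_coverage()].
#' @param protein_coding_only in `core` mode, additionally restrict to
#'   transcripts annotated `protein_coding` (default off: the coverage rule
#'   alone is the selector).
#' @return a `core_selection`: list with `gene_id`, `mode`, `threshold`,
#'   `selected_exon_ids` and `measurable` (`FALSE` when the selection is
#'   empty, i.e. the gene signal cannot be computed under this rule).
#' @export
select_core_exons <- function(model, mode = c("core", "total", "all"),
                              threshold = 0.60,
                              metric = c("span", "exonic"),
                              protein_coding_only = FALSE) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  if (is.list(model) && !inherits(model, "gene_model"))
    return(lapply(model, select_core_exons, mode = mode,
                  threshold = threshold, metric = metric,
                  protein_coding_only = protein_coding_only))
  stopifnot(inherits(model, "gene_model"))
  stopifnot(is.numeric(threshold), threshold > 0, threshold <= 1)

  txs <- model$transcripts
  if (mode == "all") {
    sel <- model$exons$exon_id
  } else {
    if (mode == "core") {
      cov <- vapply(names(txs), function(tx)
        transcript_coverage(model, tx, metric), numeric(1))
      keep <- cov >= threshold
      if (protein_coding_only) {
        pc <- !is.na(model$biotypes) & model$biotypes == "protein_coding"
        if (any(keep & pc)) keep <- keep & pc
      }
      if (!any(keep)) {
        warning("gene ", model$gene_id, ": no transcript covers >= ",
                threshold, " of the locus; falling back to the transcript ",
                "with maximal coverage (", names(txs)[which.max(cov)], ")")
        keep <- seq_along(txs) == which.max(cov)
      }
      txs <- txs[keep]
    }
    sel <- Reduce(intersect, txs)
  }
  sel <- model$exons$exon_id[model$exons$exon_id %in% sel]  # genomic order
  structure(list(gene_id = model$gene_id, mode = mode,
                 threshold = if (mode == "core") threshold else NA_real_,
                 selected_exon_ids = sel,
                 measurable = length(sel) > 0L),
            class = "core_selection")
}

#' @export
print.core_selection <- function(x, ...) {
  cat(sprintf("Core selection for %s (mode=%s%s): %d exon(s)%s\n",
              x$gene_id, x$mode,
              if (!is.na(x$threshold)) sprintf(", threshold=%.2f", x$threshold)
              else "",
              length(x$selected_exon_ids),
              if (!x$measurable) " -- gene signal not measurable" else ""))
  if (x$measurable)
    cat("  ", paste(x$selected_exon_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate core selections over a set of gene models
#'
#' @param models list of `gene_model` objects.
#' @inheritParams select_core_exons
#' @return data.frame with one row per gene: `gene_id`, `mode`,
#'   `n_exons_selected`, `measurable`, `selected_exon_ids`
#'   (comma-separated).
#' @export
core_selection_table <- function(models, mode = c("core", "total", "all"),
                                 threshold = 0.60) {
  mode <- match.arg(mode)
  sels <- select_core_exons(models, mode = mode, threshold = threshold)
  data.frame(
    gene_id = vapply(sels, `[[`, character(1), "gene_id"),
    mode = mode,
    n_exons_selected = vapply(sels, function(s)
      length(s$selected_exon_ids), integer(1)),
    measurable = vapply(sels, `[[`, logical(1), "measurable"),
    selected_exon_ids = vapply(sels, function(s)
      paste(s$selected_exon_ids, collapse = ","), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Merge exons measured by identical probe sets
#'
#' When a probe mapping is available, two partially overlapping exons are
#' operationally the same exon iff they are interrogated by the same probes.
#' This merges such exons in a gene model (the lexicographically first exon
#' id is kept; transcript memberships are rewritten accordingly).
#'
#' @param model a `gene_model`.
#' @param mapping probe mapping data.frame with columns `probe_id`,
#'   `gene_id`, `exon_id` (and optionally `ambiguous`; ambiguous probes are
#'   ignored).
#' @return the updated `gene_model`.
#' @export
merge_exons_by_probes <- function(model, mapping) {
  stopifnot(inherits(model, "gene_model"))
  mapping <- .check_mapping(mapping)
  m <- mapping[mapping$gene_id == model$gene_id & !mapping$ambiguous, ,
               drop = FALSE]
  m <- m[m$exon_id %in% model$exons$exon_id, , drop = FALSE]
  if (nrow(m) == 0L) return(model)
  sig <- vapply(split(m$probe_id, m$exon_id),
                function(p) paste(sort(unique(p)), collapse = ";"),
                character(1))
  canon <- tapply(names(sig), sig, function(ids) sort(ids)[1L])
  rename <- stats::setNames(unname(canon[sig]), names(sig))
  apply_rename <- function(ids) {
    hit <- ids %in% names(rename)
    ids[hit] <- rename[ids[hit]]
    unique(ids)
  }
  ex <- model$exons
  ex$exon_id <- ifelse(ex$exon_id %in% names(rename),
                       rename[ex$exon_id], ex$exon_id)
  # keep one record per merged exon, spanning the merged coordinates
  ex <- do.call(rbind, lapply(split(ex, ex$exon_id), function(g)
    data.frame(exon_id = g$exon_id[1L], chrom = g$chrom[1L],
               start = min(g$start), end = max(g$end),
               strand = g$strand[1L], stringsAsFactors = FALSE)))
  rownames(ex) <- NULL
  txs <- lapply(model$transcripts, apply_rename)
  new_gene_model(model$gene_id, ex, txs, model$biotypes)
}
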