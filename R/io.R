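#' Construct a CoipExperiment from a signal matrix
#'
#' @param signal Numeric matrix, proteins x channels. Columns are reordered
#'   to the design's channel order (they must cover all design channels).
#' @param design A [CoipDesign-class].
#' @param nPeptides Integer vector of peptide counts per protein.
#' @param geneSymbol Optional character vector (defaults to rownames).
#' @param isContaminant,isDecoy Optional logical vectors (default all FALSE).
#' @return A [CoipExperiment-class].
#' @export
CoipExperiment <- function(signal, design, nPeptides,
                           geneSymbol = rownames(signal),
                           isContaminant = logical(nrow(signal)),
                           isDecoy = logical(nrow(signal))) {
  stopifnot(is(design, "CoipDesign"), is.matrix(signal))
  ids <- channelIds(design)
  miss <- setdiff(ids, colnames(signal))
  if (length(miss))
    stop("signal matrix lacks channel column(s): ", paste(miss, collapse = ", "))
  signal <- signal[, ids, drop = FALSE]
  rd <- S4Vectors::DataFrame(gene_symbol = as.character(geneSymbol),
                             n_peptides = as.integer(nPeptides),
                             is_contaminant = as.logical(isContaminant),
                             is_decoy = as.logical(isDecoy),
                             row.names = rownames(signal))
  se <- SummarizedExperiment(assays = list(signal = signal), rowData = rd)
  new("CoipExperiment", se, design = design)
}

.flag_col <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- trimws(as.character(x))
  x %in% c("+", "TRUE", "true", "1", "yes")
}

# Resolve one logical column from a vector of alias names; NULL if absent.
.find_col <- function(df, aliases) {
  hit <- aliases[aliases %in% colnames(df)]
  if (length(hit)) df[[hit[1]]] else NULL
}

# Locate the per-channel signal columns of a search-engine table. One naming
# scheme must cover every design channel; schemes are tried in order:
# "signal <id>" / "intensity <id>" / bare "<id>" (id = channel label), then
# "Reporter intensity [corrected] <i>" with i the design position (1-based,
# with a 0-based fallback for tools that count from zero).
.signal_columns <- function(df, design) {
  ids <- channelIds(design)
  n <- length(ids)
  cn <- colnames(df)
  norm <- function(s) gsub("[. ]+", " ", s)
  schemes <- list(paste("signal", ids),
                  paste("intensity", ids),
                  ids,
                  paste("Reporter intensity corrected", seq_len(n)),
                  paste("Reporter intensity corrected", seq_len(n) - 1L),
                  paste("Reporter intensity", seq_len(n)),
                  paste("Reporter intensity", seq_len(n) - 1L))
  for (cand in schemes) {
    hit <- cn[match(norm(cand), norm(cn))]
    if (!anyNA(hit)) return(hit)
  }
  stop("no signal column found for channel '", ids[1],
       "' (tried e.g. 'signal ", ids[1], "', 'Reporter intensity corrected 1')")
}

.parse_signals <- function(df, cols, ids, path) {
  sig <- matrix(NA_real_, nrow(df), length(cols),
                dimnames = list(NULL, ids))
  for (j in seq_along(cols)) {
    v <- suppressWarnings(as.numeric(df[[cols[j]]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad))
      stop(sprintf("%s: column '%s', line %d: signal not a non-negative number",
                   path, cols[j], bad[1] + 1L))
    sig[, j] <- v
  }
  sig
}

#' Read a protein-group table
#'
#' Reads a tab-separated search-engine protein-group table (UTF-8, header
#' row). Required columns: a protein id, a peptide count, and one signal
#' column per design channel; a built-in alias map covers both the generic
#' \code{signal <channel_id>} dialect and the
#' \code{Reporter intensity corrected N} style. Contaminant/decoy flags use
#' the \code{"+"} / \code{""} convention and the flagged rows are retained
#' but marked (downstream steps exclude them by default).
#'
#' @param path Path to the TSV file.
#' @param design A [CoipDesign-class]; channel columns are mapped through it.
#' @return A [CoipExperiment-class], one row per table row.
#' @seealso [relativeAbundance()], [writeResults()]
#' @export
readProteinGroups <- function(path, design) {
  stopifnot(is(design, "CoipDesign"))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  pid <- .find_col(df, c("protein_id", "Protein IDs", "Majority protein IDs"))
  if (is.null(pid)) stop(path, ": missing required column 'protein_id'")
  npep <- .find_col(df, c("n_peptides", "Peptides", "Unique peptides"))
  if (is.null(npep)) stop(path, ": missing required column 'n_peptides'")
  gene <- .find_col(df, c("gene_symbol", "Gene names"))
  if (is.null(gene)) gene <- as.character(pid)
  contam <- .find_col(df, c("is_contaminant", "Potential contaminant"))
  decoy <- .find_col(df, c("is_decoy", "Reverse"))
  ids <- channelIds(design)
  cols <- .signal_columns(df, design)
  sig <- .parse_signals(df, cols, ids, path)
  rownames(sig) <- as.character(pid)
  CoipExperiment(sig, design,
                 nPeptides = suppressWarnings(as.integer(npep)),
                 geneSymbol = as.character(gene),
                 isContaminant = if (is.null(contam)) logical(nrow(df)) else .flag_col(contam),
                 isDecoy = if (is.null(decoy)) logical(nrow(df)) else .flag_col(decoy))
}

#' Read a PSM (peptide-spectrum match) table
#'
#' Tab-separated, one row per PSM, with columns \code{psm_id},
#' \code{protein_id}, \code{peptide_sequence}, \code{injection_time} (ms),
#' label flags \code{has_nterm_label} / \code{has_lysine_label} (\code{"+"} /
#' \code{""} or logical), and one reporter-intensity column per channel
#' (same aliases as [readProteinGroups()]).
#'
#' @param path Path to the TSV file.
#' @param design A [CoipDesign-class].
#' @return A data.frame with one \code{intensity.<channel_id>} column per
#'   channel, suitable for [proteinSignalFromPsms()] and
#'   [labelingEfficiency()].
#' @export
readPsmTable <- function(path, design) {
  stopifnot(is(design, "CoipDesign"))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("psm_id", "protein_id", "peptide_sequence", "injection_time")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop(path, ": missing required column(s): ", paste(miss, collapse = ", "))
  it <- suppressWarnings(as.numeric(df$injection_time))
  bad <- which(is.na(it) | it <= 0)
  if (length(bad))
    stop(sprintf("%s: line %d: injection_time must be > 0", path, bad[1] + 1L))
  ids <- channelIds(design)
  cols <- .signal_columns(df, design)
  sig <- .parse_signals(df, cols, ids, path)
  colnames(sig) <- paste0("intensity.", ids)
  out <- data.frame(psm_id = as.character(df$psm_id),
                    protein_id = as.character(df$protein_id),
                    peptide_sequence = as.character(df$peptide_sequence),
                    injection_time = it,
                    has_nterm_label = if (is.null(.find_col(df, "has_nterm_label")))
                      logical(nrow(df)) else .flag_col(df$has_nterm_label),
                    has_lysine_label = if (is.null(.find_col(df, "has_lysine_label")))
                      logical(nrow(df)) else .flag_col(df$has_lysine_label),
                    stringsAsFactors = FALSE, check.names = FALSE)
  cbind(out, as.data.frame(sig, optional = TRUE, check.names = FALSE))
}

#' Write (and re-read) pipeline results
#'
#' Emits two files under \code{prefix}: \code{<prefix>_enrichment.tsv}, a
#' per-protein table of fold-enrichment ratios, peptide counts and membership
#' flags; and \code{<prefix>_result.json}, a structured document with the
#' cutoffs, set sizes and members, pseudocounts, and (optionally) the
#' pairwise overlap statistics. JSON numbers keep full precision so that
#' re-reading reproduces every numeric field.
#'
#' @param result An [InteractomeResult-class].
#' @param enrichment The [EnrichmentTable-class] behind it.
#' @param prefix Output path prefix (directories are created).
#' @param overlaps Optional overlap data.frame from
#'   [pairwiseOverlapMatrix()].
#' @return Invisibly, the two file paths.
#' @seealso [readResults()]
#' @export
writeResults <- function(result, enrichment, prefix, overlaps = NULL) {
  stopifnot(is(result, "InteractomeResult"), is(enrichment, "EnrichmentTable"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  tsv <- paste0(prefix, "_enrichment.tsv")
  jsonf <- paste0(prefix, "_result.json")

  rat <- enrichment@ratios
  tab <- data.frame(protein_id = rownames(rat),
                    n_peptides = enrichment@nPeptides[rownames(rat)],
                    rat, check.names = FALSE, stringsAsFactors = FALSE)
  for (s in colnames(rat))
    tab[[paste0("enriched.", s)]] <- tab$protein_id %in% result@enrichedSets[[s]]
  tab$in_interactome <- tab$protein_id %in% result@interactome
  tab$in_background <- tab$protein_id %in% result@background
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  cut <- result@cutoffs
  doc <- list(
    cutoffs = list(theta = as.list(cut@theta), q = cut@q,
                   min_peptides = cut@minPeptides, scope = cut@scope,
                   strict = result@strict),
    pseudocount = as.list(enrichment@pseudocount),
    enriched_sets = lapply(result@enrichedSets, as.list),
    enriched_sizes = lapply(result@enrichedSets, length),
    interactome = as.list(result@interactome),
    interactome_size = length(result@interactome),
    background = as.list(result@background),
    background_size = length(result@background))
  if (!is.null(overlaps)) doc$overlaps <- overlaps
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              null = "null"), jsonf)
  invisible(c(tsv = tsv, json = jsonf))
}

#' Reload a results JSON written by [writeResults()]
#'
#' @param path Path to the \code{*_result.json} file.
#' @return A list with character-vector sets (\code{enriched_sets},
#'   \code{interactome}, \code{background}), the cutoff record, pseudocounts
#'   and any overlap table.
#' @export
readResults <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  doc$interactome <- as.character(unlist(doc$interactome))
  doc$background <- as.character(unlist(doc$background))
  doc$enriched_sets <- lapply(doc$enriched_sets,
                              function(s) as.character(unlist(s)))
  doc$cutoffs$theta <- unlist(doc$cutoffs$theta)
  doc$pseudocount <- unlist(doc$pseudocount)
  doc
}

#' Read annotation sets (two-column TSV or GMT)
#'
#' Two-column format: header \code{annotation_name<TAB>protein_id}, one
#' membership pair per row. GMT format: one set per line,
#' \code{name<TAB>description<TAB>member...}.
#'
#' @param path Path to the file.
#' @param format \code{"auto"} (sniff), \code{"tsv"} or \code{"gmt"}.
#' @return Named list of character vectors.
#' @seealso [annotationEnrichment()]
#' @export
readAnnotationSets <- function(path, format = c("auto", "tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  }
  if (format == "gmt") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- vapply(parts, `[[`, "", 1L)
    return(sets)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("annotation_name", "protein_id") %in% colnames(df)))
    stop(path, ": expected columns 'annotation_name' and 'protein_id'")
  lapply(split(df$protein_id, df$annotation_name), unique)
}
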