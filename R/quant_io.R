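# Data model, readers and record-level filtering for protein-intensity
# tables and annotation lists.

#' Build a sample-design table
#'
#' Expands the user-supplied design (sample id, condition label,
#' replicate, bait) with derived columns: HS/recovery minutes, phase,
#' and the three-level covariate group used for batch correction
#' (HS0/HS10 = early, HS20--HS60 = middle, HS120--Re10 = late; the
#' unstressed condensate condition carries no group).
#'
#' @param sample_id character, unique sample identifiers.
#' @param time_label character, one of HS0, HS10, HS20, HS30, HS60,
#'   HS120, HS180, Re5, Re10, SGls.
#' @param replicate integer replicate index (>= 1).
#' @param bait character, "G3BP1" or "CAPRIN1". The SGls condition is
#'   only measured in the G3BP1 pull-down.
#' @return data.frame with columns sample_id, time_label, minutes,
#'   phase, replicate, bait, combat_group.
#' @export
sample_design <- function(sample_id, time_label, replicate, bait) {
  time_label <- as.character(time_label)
  bait <- as.character(bait)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  bad <- setdiff(time_label, ALL_LABELS)
  if (length(bad))
    stop("unknown time_label: ", paste(unique(bad), collapse = ", "))
  if (!all(bait %in% c("G3BP1", "CAPRIN1")))
    stop("bait must be G3BP1 or CAPRIN1")
  if (any(time_label == "SGls" & bait != "G3BP1"))
    stop("SGls samples occur only in the G3BP1 pull-down")
  replicate <- as.integer(replicate)
  if (any(is.na(replicate)) || any(replicate < 1L))
    stop("replicate must be an integer >= 1")
  data.frame(
    sample_id = as.character(sample_id),
    time_label = time_label,
    minutes = minutes_of(time_label),
    phase = phase_of(time_label),
    replicate = replicate,
    bait = bait,
    combat_group = combat_group_of(time_label),
    stringsAsFactors = FALSE
  )
}

#' Construct a quantitative intensity matrix
#'
#' Container pairing a proteins x samples intensity matrix with its
#' protein records and sample design. Missing intensities are allowed
#' (NA); retained finite values must be non-negative.
#'
#' @param values numeric matrix, proteins x samples; rownames are
#'   accessions, colnames are sample ids.
#' @param records data.frame with at least accession and gene_name;
#'   optional columns is_mitochondrial, is_keratin, fdr_confidence,
#'   unique_peptides (list column of per-replicate integer counts).
#' @param samples a [sample_design()] table covering every column.
#' @return object of class `quant_matrix`.
#' @export
quant_matrix <- function(values, records, samples) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != nrow(records))
    stop("values has ", nrow(values), " rows but records has ",
         nrow(records))
  if (ncol(values) != nrow(samples))
    stop("values has ", ncol(values), " columns but samples has ",
         nrow(samples), " rows")
  if (anyDuplicated(records$accession))
    stop("duplicate accession: ",
         paste(unique(records$accession[duplicated(records$accession)]),
               collapse = ", "))
  rownames(values) <- records$accession
  colnames(values) <- samples$sample_id
  if (any(values < 0, na.rm = TRUE))
    stop("negative intensities are not allowed")
  structure(list(values = values, records = records, samples = samples),
            class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat("quant_matrix: ", nrow(x$values), " proteins x ",
      ncol(x$values), " samples\n", sep = "")
  cat("  baits: ", paste(unique(x$samples$bait), collapse = ", "),
      "; replicates: ", paste(sort(unique(x$samples$replicate)),
                              collapse = ", "), "\n", sep = "")
  cat("  conditions: ",
      paste(intersect(ALL_LABELS, unique(x$samples$time_label)),
            collapse = " "), "\n", sep = "")
  cat("  missing values: ", sum(is.na(x$values)), "\n", sep = "")
  invisible(x)
}

#' Subset a quant_matrix by proteins and/or samples
#' @param m a quant_matrix.
#' @param proteins accession vector (default all).
#' @param samples logical/character/integer index on samples (default all).
#' @return quant_matrix.
#' @export
subset_quant <- function(m, proteins = NULL, samples = NULL) {
  stopifnot(inherits(m, "quant_matrix"))
  ri <- if (is.null(proteins)) seq_len(nrow(m$values)) else
    match(proteins, m$records$accession)
  if (anyNA(ri)) stop("unknown accession in subset")
  ci <- if (is.null(samples)) seq_len(ncol(m$values)) else samples
  if (is.character(ci)) ci <- match(ci, m$samples$sample_id)
  quant_matrix(m$values[ri, ci, drop = FALSE],
               m$records[ri, , drop = FALSE],
               m$samples[ci, , drop = FALSE])
}

RECORD_COLUMNS <- c("accession", "gene_name", "is_mitochondrial",
                    "is_keratin", "fdr_confidence", "unique_peptides")

#' Read a quantitative proteomics table with its sample design
#'
#' The quant table is TSV with one header row: the record columns
#' (accession, gene_name, is_mitochondrial, is_keratin, fdr_confidence,
#' unique_peptides with per-replicate counts joined by ";") followed by
#' one intensity column per sample id in the design table. "NA" cells
#' are preserved as missing.
#'
#' @param path TSV quant table.
#' @param design_path TSV with columns sample_id, time_label,
#'   replicate, bait.
#' @return quant_matrix.
#' @export
read_quant_table <- function(path, design_path) {
  des <- read.delim(design_path, stringsAsFactors = FALSE,
                    check.names = FALSE)
  need <- c("sample_id", "time_label", "replicate", "bait")
  miss <- setdiff(need, names(des))
  if (length(miss))
    stop("design table is missing column(s): ",
         paste(miss, collapse = ", "))
  samples <- sample_design(des$sample_id, des$time_label,
                           des$replicate, des$bait)

  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  miss <- setdiff(RECORD_COLUMNS, names(tab))
  if (length(miss))
    stop("quant table is missing record column(s): ",
         paste(miss, collapse = ", "))
  value_cols <- setdiff(names(tab), RECORD_COLUMNS)
  unknown <- setdiff(value_cols, samples$sample_id)
  if (length(unknown))
    stop("sample column(s) absent from design: ",
         paste(unknown, collapse = ", "))
  absent <- setdiff(samples$sample_id, value_cols)
  if (length(absent))
    stop("design sample(s) absent from quant table: ",
         paste(absent, collapse = ", "))
  if (anyDuplicated(tab$accession))
    stop("duplicate accession in quant table: ",
         paste(unique(tab$accession[duplicated(tab$accession)]),
               collapse = ", "))

  vals <- vapply(samples$sample_id, function(s) {
    v <- suppressWarnings(as.numeric(tab[[s]]))
    bad <- which(!is.na(tab[[s]]) & tab[[s]] != "NA" &
                   nzchar(tab[[s]]) & is.na(v))
    if (length(bad))
      stop("non-numeric value in column '", s, "', row ", bad[1],
           ": '", tab[[s]][bad[1]], "'")
    v
  }, numeric(nrow(tab)))
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(tab$accession, samples$sample_id))

  records <- data.frame(
    accession = tab$accession,
    gene_name = tab$gene_name,
    is_mitochondrial = as.logical(tab$is_mitochondrial),
    is_keratin = as.logical(tab$is_keratin),
    fdr_confidence = tab$fdr_confidence,
    stringsAsFactors = FALSE
  )
  records$unique_peptides <- lapply(strsplit(tab$unique_peptides, ";",
                                             fixed = TRUE),
                                    function(x) as.integer(x))
  quant_matrix(vals, records, samples)
}

#' Write a quant_matrix to a TSV quant table (round-trip safe)
#'
#' Finite intensities are written with 17 significant digits so a
#' write/read cycle reproduces them bit-identically; missing values are
#' written as "NA".
#'
#' @param m quant_matrix.
#' @param path output TSV path.
#' @param design_path optional path for the matching design TSV.
#' @return invisibly, `path`.
#' @export
write_quant_table <- function(m, path, design_path = NULL) {
  stopifnot(inherits(m, "quant_matrix"))
  rec <- m$records
  out <- data.frame(
    accession = rec$accession,
    gene_name = rec$gene_name,
    is_mitochondrial = if (!is.null(rec$is_mitochondrial))
      rec$is_mitochondrial else FALSE,
    is_keratin = if (!is.null(rec$is_keratin)) rec$is_keratin else FALSE,
    fdr_confidence = if (!is.null(rec$fdr_confidence))
      rec$fdr_confidence else "high",
    unique_peptides = if (!is.null(rec$unique_peptides))
      vapply(rec$unique_peptides, paste, "", collapse = ";") else "1",
    stringsAsFactors = FALSE, check.names = FALSE
  )
  vchar <- matrix(sprintf("%.17g", m$values), nrow = nrow(m$values))
  vchar[is.na(m$values)] <- "NA"
  colnames(vchar) <- m$samples$sample_id
  out <- cbind(out, as.data.frame(vchar, stringsAsFactors = FALSE,
                                  check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(design_path))
    write.table(m$samples[, c("sample_id", "time_label", "replicate",
                              "bait")],
                design_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' Record-level prefiltering of a quant matrix
#'
#' Removes proteins failing any of: non-high FDR confidence; any
#' replicate with fewer than `min_unique_peptides` unique peptides;
#' mitochondrial; keratin; missing gene name. Mitochondrial/keratin
#' status must be supplied as record flags (or via a sidecar gene
#' list applied by the caller); it is never guessed from sequence.
#'
#' @param m quant_matrix with populated record flags.
#' @param min_unique_peptides minimum unique peptides required in
#'   every replicate (default 1).
#' @param require_high_fdr drop records whose fdr_confidence is not
#'   "high" (default TRUE).
#' @return filtered quant_matrix; attribute `removal_tally` counts,
#'   per rule, how many input records failed it (a record failing two
#'   rules is counted in both).
#' @export
prefilter_records <- function(m, min_unique_peptides = 1,
                              require_high_fdr = TRUE) {
  stopifnot(inherits(m, "quant_matrix"))
  rec <- m$records
  fail_fdr <- if (require_high_fdr)
    is.na(rec$fdr_confidence) | rec$fdr_confidence != "high"
  else rep(FALSE, nrow(rec))
  fail_pep <- vapply(rec$unique_peptides, function(x)
    length(x) == 0 || any(is.na(x)) || any(x < min_unique_peptides),
    logical(1))
  fail_mito <- isTRUE_vec(rec$is_mitochondrial)
  fail_ker <- isTRUE_vec(rec$is_keratin)
  fail_gene <- is.na(rec$gene_name) | !nzchar(trimws(rec$gene_name))
  keep <- !(fail_fdr | fail_pep | fail_mito | fail_ker | fail_gene)
  out <- quant_matrix(m$values[keep, , drop = FALSE],
                      rec[keep, , drop = FALSE], m$samples)
  attr(out, "removal_tally") <- c(
    fdr_confidence = sum(fail_fdr),
    unique_peptides = sum(fail_pep),
    mitochondrial = sum(fail_mito),
    keratin = sum(fail_ker),
    missing_gene_name = sum(fail_gene)
  )
  out
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

#' Read a gene list (one symbol per line, "#" comments allowed)
#' @param path text file.
#' @return character vector of symbols (whitespace-stripped, deduplicated).
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x <- x[nzchar(x)]
  if (!length(x)) stop("empty gene list: ", path)
  unique(x)
}

#' Flag membership of gene symbols in a reference list
#'
#' Case-insensitive exact symbol match after whitespace stripping; no
#' alias expansion. Used e.g. for previously-reported SG constituents
#' and RNA-binding-protein annotations.
#'
#' @param gene_names character vector of query symbols.
#' @param reference path to a gene-list file, or a character vector.
#' @return named logical vector (one per query); attribute `n_overlap`
#'   holds the number of distinct query symbols present in the
#'   reference.
#' @export
annotate_membership <- function(gene_names, reference) {
  ref <- if (length(reference) == 1 && file.exists(reference))
    read_gene_list(reference) else as.character(reference)
  if (!length(ref)) stop("empty reference list")
  ref_key <- unique(toupper(trimws(ref)))
  key <- toupper(trimws(gene_names))
  flags <- key %in% ref_key
  names(flags) <- gene_names
  attr(flags, "n_overlap") <- length(unique(key[flags]))
  flags
}
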