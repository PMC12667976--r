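# Readers and writers for the delimited tables flowing through the
# pipeline: variant counts, functional scores (MaveDB-flavoured), clinical
# reference sets, per-residue structural annotations, and patient cohorts.
# All files are TSV with a header row; unknown columns are preserved and
# row order is stable across a write -> read round trip.

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, " is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(df)
}

#' Read a variant count table
#'
#' Expects one row per codon-level change per sequencing condition,
#' replicate and tile, with columns \code{region}, \code{replicate},
#' \code{condition} (one of \code{select}, \code{nonselect},
#' \code{wt_select}, \code{wt_nonselect}), \code{tile}, \code{codon_index},
#' \code{ref_codon}, \code{alt_codon}, \code{count}, \code{depth}. The
#' wild-type (\code{wt_*}) conditions carry apparent variant counts from
#' sequencing an unmutagenized template and estimate base-call error.
#'
#' Validation rejects: missing mandatory columns, \code{count > depth},
#' \code{depth <= 0}, \code{ref_codon == alt_codon}, non-triplet codons,
#' and duplicate \code{(condition, replicate, tile, codon_index,
#' alt_codon)} keys, reporting the offending row numbers.
#'
#' @param path TSV file path.
#' @return A validated data.frame of counts.
#' @export
read_count_table <- function(path) {
  df <- .read_tsv(path)
  validate_count_table(df, what = paste0("count table '", path, "'"))
}

#' Validate a count table already in memory
#'
#' @param df Count data.frame (see \code{\link{read_count_table}}).
#' @param what Label used in error messages.
#' @return \code{df}, invisibly validated (returned visibly).
#' @export
validate_count_table <- function(df, what = "count table") {
  .require_columns(df, c("region", "replicate", "condition", "tile",
                         "codon_index", "ref_codon", "alt_codon",
                         "count", "depth"), what)
  bad_cond <- which(!df$condition %in%
                      c("select", "nonselect", "wt_select", "wt_nonselect"))
  if (length(bad_cond))
    stop(what, ": unknown condition in row(s) ",
         paste(utils::head(bad_cond, 10), collapse = ", "), call. = FALSE)
  bad_depth <- which(!is.finite(df$depth) | df$depth <= 0)
  if (length(bad_depth))
    stop(what, ": depth must be > 0; offending row(s) ",
         paste(utils::head(bad_depth, 10), collapse = ", "), call. = FALSE)
  bad_count <- which(!is.finite(df$count) | df$count < 0 |
                       df$count > df$depth)
  if (length(bad_count))
    stop(what, ": count must lie in [0, depth]; offending row(s) ",
         paste(utils::head(bad_count, 10), collapse = ", "), call. = FALSE)
  bad_codon <- which(nchar(df$ref_codon) != 3L | nchar(df$alt_codon) != 3L |
                       grepl("[^ACGT]", df$ref_codon) |
                       grepl("[^ACGT]", df$alt_codon) |
                       df$ref_codon == df$alt_codon)
  if (length(bad_codon))
    stop(what, ": invalid ref/alt codon pair in row(s) ",
         paste(utils::head(bad_codon, 10), collapse = ", "), call. = FALSE)
  key <- paste(df$condition, df$replicate, df$tile, df$codon_index,
               df$alt_codon, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop(what, ": duplicate (condition, replicate, tile, codon) key in ",
         "row(s) ", paste(utils::head(dup, 10), collapse = ", "),
         call. = FALSE)
  df
}

#' Write a variant count table
#' @param df Count data.frame.
#' @param path Output TSV path.
#' @export
write_count_table <- function(df, path) {
  validate_count_table(df)
  .write_tsv(df, path)
}

#' Read a functional score table
#'
#' MaveDB-flavoured scores: \code{hgvs_pro}, \code{score}, \code{se},
#' \code{in_both_replicates}, \code{snv_accessible},
#' \code{n_codon_measurements}, plus optional \code{llrp}, \code{evidence}
#' and \code{caution} columns added by calibration. Extra columns are kept.
#'
#' @param path TSV file path.
#' @return Score data.frame.
#' @export
read_score_table <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("hgvs_pro", "score", "se"),
                   paste0("score table '", path, "'"))
  bad <- which(is.finite(df$se) & df$se < 0)
  if (length(bad))
    stop("score table '", path, "': negative se in row(s) ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  for (col in c("in_both_replicates", "snv_accessible", "caution"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  df
}

#' Write a functional score table
#' @param df Score data.frame (needs \code{hgvs_pro}, \code{score}, \code{se}).
#' @param path Output TSV path.
#' @export
write_score_table <- function(df, path) {
  .require_columns(df, c("hgvs_pro", "score", "se"), "score table")
  .write_tsv(df, path)
}

#' Read a clinical reference-variant set
#'
#' Columns: \code{hgvs_pro}, \code{label} in \code{P}, \code{LP} (positive)
#' or \code{B}, \code{LB} (negative), and \code{stars} (ClinVar-style
#' review level). Rows below \code{stars_min} are dropped, mirroring the
#' practice of filtering reference sets on at least one review star; the
#' exclusions are reported via a message.
#'
#' @param path TSV file path.
#' @param stars_min Minimum review stars to retain (default 1).
#' @return Data.frame with an added logical \code{positive} column.
#' @export
read_reference_set <- function(path, stars_min = 1) {
  df <- .read_tsv(path)
  .require_columns(df, c("hgvs_pro", "label", "stars"),
                   paste0("reference set '", path, "'"))
  bad <- which(!df$label %in% c("P", "LP", "B", "LB"))
  if (length(bad))
    stop("reference set '", path, "': label must be P/LP/B/LB; row(s) ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  drop <- which(df$stars < stars_min)
  if (length(drop)) {
    message("read_reference_set: excluding ", length(drop),
            " variant(s) below ", stars_min, " review star(s): ",
            paste(utils::head(df$hgvs_pro[drop], 10), collapse = ", "))
    df <- df[-drop, , drop = FALSE]
    rownames(df) <- NULL
  }
  df$positive <- df$label %in% c("P", "LP")
  df
}

#' Write a reference-variant set
#' @param df Data.frame with \code{hgvs_pro}, \code{label}, \code{stars}.
#' @param path Output TSV path.
#' @export
write_reference_set <- function(df, path) {
  .require_columns(df, c("hgvs_pro", "label", "stars"), "reference set")
  .write_tsv(df[setdiff(names(df), "positive")], path)
}

#' Read a per-residue annotation table
#'
#' Columns: \code{position}, \code{asa} (accessible surface area in
#' square Angstroms), \code{disorder} (logical), \code{domain} (optional
#' label). A \code{burial_class} column is derived: \code{buried} when
#' \code{asa < buried_max}, \code{surface} when \code{asa > surface_min},
#' otherwise \code{intermediate}.
#'
#' @param path TSV file path.
#' @param buried_max ASA below which a residue is called buried
#'   (default 50).
#' @param surface_min ASA above which a residue is called surface
#'   (default 110).
#' @return Annotation data.frame with derived \code{burial_class}.
#' @export
read_annotations <- function(path, buried_max = 50, surface_min = 110) {
  df <- .read_tsv(path)
  .require_columns(df, c("position", "asa"),
                   paste0("annotation table '", path, "'"))
  if ("disorder" %in% names(df)) df$disorder <- as.logical(df$disorder)
  df$burial_class <- burial_class(df$asa, buried_max, surface_min)
  df
}

#' Classify residues as buried / intermediate / surface by ASA
#' @param asa Numeric accessible surface area (square Angstroms).
#' @inheritParams read_annotations
#' @return Character vector over \code{buried}, \code{intermediate},
#'   \code{surface} (\code{NA} for missing ASA).
#' @export
burial_class <- function(asa, buried_max = 50, surface_min = 110) {
  ifelse(is.na(asa), NA_character_,
         ifelse(asa < buried_max, "buried",
                ifelse(asa > surface_min, "surface", "intermediate")))
}

#' Read a patient cohort table
#'
#' Columns: \code{patient_id}, \code{allele1}, \code{allele2} (each
#' \code{"WT"}, \code{"truncating"}, or one or more protein-variant HGVS
#' strings joined by \code{";"}), and \code{symptoms} (labels joined by
#' \code{";"}, possibly empty). Allele and symptom fields are split into
#' list-columns.
#'
#' @param path TSV file path.
#' @return Cohort data.frame with list-columns \code{allele1},
#'   \code{allele2} and \code{symptoms}.
#' @export
read_cohort_table <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("patient_id", "allele1", "allele2", "symptoms"),
                   paste0("cohort table '", path, "'"))
  split_field <- function(x) {
    lapply(x, function(s) {
      if (is.na(s) || s == "") character(0)
      else trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  }
  df$allele1 <- split_field(df$allele1)
  df$allele2 <- split_field(df$allele2)
  df$symptoms <- split_field(df$symptoms)
  df
}

#' Write a patient cohort table
#' @param df Cohort data.frame as returned by \code{\link{read_cohort_table}}.
#' @param path Output TSV path.
#' @export
write_cohort_table <- function(df, path) {
  .require_columns(df, c("patient_id", "allele1", "allele2", "symptoms"),
                   "cohort table")
  out <- df
  join <- function(x) vapply(x, paste, character(1), collapse = ";")
  for (col in c("allele1", "allele2", "symptoms"))
    if (is.list(out[[col]])) out[[col]] <- join(out[[col]])
  .write_tsv(out, path)
}

#' Read an in-frame CDS from a FASTA file
#'
#' Minimal single-record FASTA reader for coding sequences used by
#' \code{\link{snv_accessible_substitutions}}.
#'
#' @param path FASTA file path (first record used).
#' @return Character scalar nucleotide sequence, upper case.
#' @export
read_cds_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  headers <- grep("^>", lines)
  if (!length(headers) || headers[1] != 1L)
    stop("'", path, "' does not look like a FASTA file", call. = FALSE)
  end <- if (length(headers) > 1L) headers[2] - 1L else length(lines)
  toupper(paste(lines[2:end], collapse = ""))
}
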