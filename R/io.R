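#' Read miRNA-disease-type association records
#'
#' Reads a tab-separated file whose first three columns are miRNA name,
#' disease name and evidence category (an optional fourth column is kept as a
#' source identifier, e.g. a PMID). Names are normalized (case-fold, trim,
#' collapse whitespace), precursor names are optionally collapsed to mature
#' names via `mapping`, category strings are matched through `synonyms`, and
#' duplicate (miRNA, disease, type) triples are removed. Records whose
#' category cannot be mapped are dropped with a warning giving the count.
#'
#' @param path path to a UTF-8 TSV file with a header line.
#' @param mapping optional precursor-to-mature name table: either a named
#'   character vector (`names` = precursor, values = mature) or a two-column
#'   data frame (precursor, mature). Names are normalized before lookup.
#' @param synonyms named character vector mapping category spellings to the
#'   five canonical types; see [type_synonyms()].
#' @return A data frame of class `"md_associations"` with columns `mirna`,
#'   `disease`, `type` and `source_id` (NA when absent), one row per unique
#'   triple.
#' @export
read_associations <- function(path, mapping = NULL, synonyms = type_synonyms()) {
  if (!file.exists(path)) stop("association file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(raw) < 3) stop("association file needs >= 3 columns (miRNA, disease, category)")
  df <- data.frame(
    mirna = normalize_name(raw[[1]]),
    disease = normalize_name(raw[[2]]),
    type_raw = normalize_name(raw[[3]]),
    source_id = if (ncol(raw) >= 4) as.character(raw[[4]]) else NA_character_,
    stringsAsFactors = FALSE
  )
  df$mirna <- apply_name_mapping(df$mirna, mapping)
  df$type <- unname(synonyms[df$type_raw])
  bad <- is.na(df$type)
  if (any(bad)) {
    warning(sum(bad), " record(s) dropped: unrecognized category string(s): ",
            paste(unique(df$type_raw[bad]), collapse = ", "))
    df <- df[!bad, , drop = FALSE]
  }
  df$type_raw <- NULL
  dup <- duplicated(df[c("mirna", "disease", "type")])
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("md_associations", "data.frame")
  df
}

apply_name_mapping <- function(x, mapping) {
  if (is.null(mapping)) return(x)
  if (is.data.frame(mapping)) {
    map <- setNames(normalize_name(mapping[[2]]), normalize_name(mapping[[1]]))
  } else {
    map <- setNames(normalize_name(unname(mapping)), normalize_name(names(mapping)))
  }
  hit <- x %in% names(map)
  x[hit] <- unname(map[x[hit]])
  x
}

#' Write association records to TSV
#'
#' Inverse of [read_associations()]; round-trips as a set of records.
#'
#' @param assoc data frame with columns `mirna`, `disease`, `type` and
#'   optionally `source_id`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(assoc, path) {
  out <- data.frame(mirna = assoc$mirna, disease = assoc$disease,
                    category = assoc$type,
                    source_id = if ("source_id" %in% names(assoc)) assoc$source_id else NA,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a disease hierarchy as tree codes
#'
#' Reads a two-column TSV (disease name, dot-separated tree code), one row per
#' (disease, code). A disease may carry several codes, i.e. occupy several
#' positions in the hierarchy. Malformed codes are skipped with a warning.
#'
#' @param path path to a UTF-8 TSV file with a header line.
#' @return A data frame of class `"mesh_entries"` with columns `disease` and
#'   `code`, names normalized.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("tree-code file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0) {
    warning("tree-code file is empty")
    out <- data.frame(disease = character(), code = character(), stringsAsFactors = FALSE)
    class(out) <- c("mesh_entries", "data.frame")
    return(out)
  }
  if (ncol(raw) < 2) stop("tree-code file needs 2 columns (disease, tree code)")
  df <- data.frame(disease = normalize_name(raw[[1]]),
                   code = trimws(as.character(raw[[2]])),
                   stringsAsFactors = FALSE)
  ok <- grepl("^[A-Za-z0-9]+(\\.[A-Za-z0-9]+)*$", df$code)
  if (any(!ok)) {
    warning(sum(!ok), " row(s) skipped: malformed tree code(s): ",
            paste(unique(df$code[!ok]), collapse = ", "))
    df <- df[ok, , drop = FALSE]
  }
  df <- df[!duplicated(df), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("mesh_entries", "data.frame")
  df
}

#' Write tree-code entries to TSV
#' @param mesh data frame with columns `disease`, `code`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  write.table(data.frame(disease = mesh$disease, code = mesh$code),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read miRNA precursor sequences from FASTA
#'
#' The first whitespace-delimited token of each header is taken as the miRNA
#' name and normalized exactly as in [read_associations()]. DNA-style `T`
#' residues are converted to `U`; any residue outside `A/C/G/U` after
#' conversion is a fatal error naming the offending record.
#'
#' @param path path to a FASTA file.
#' @return A data frame of class `"mirna_sequences"` with columns `mirna` and
#'   `sequence` (RNA alphabet, upper case).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  nm <- normalize_name(sub("[[:space:]].*$", "", names(ss)))
  seqs <- toupper(as.character(ss))
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  bad <- grepl("[^ACGU]", seqs) | nchar(seqs) == 0
  if (any(bad)) {
    stop("non-ACGU residue (after T->U) or empty sequence in record(s): ",
         paste(nm[bad], collapse = ", "))
  }
  out <- data.frame(mirna = nm, sequence = unname(seqs), stringsAsFactors = FALSE)
  out <- out[!duplicated(out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mirna_sequences", "data.frame")
  out
}

#' Write sequences to FASTA
#' @param seqs data frame with columns `mirna`, `sequence`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(setNames(seqs$sequence, seqs$mirna))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Restrict inputs to the common entity sets
#'
#' Downstream stages only ever see miRNAs present in both the association
#' records and the FASTA, and diseases present in both the association
#' records and the tree-code table. This filtering happens once, here, and
#' the number of dropped entities is reported.
#'
#' @param assoc association records from [read_associations()].
#' @param mesh tree-code entries from [read_mesh()].
#' @param seqs sequence records from [read_fasta()].
#' @return A list of class `"md_inputs"` with elements `associations`,
#'   `mesh`, `sequences`, `mirnas`, `diseases`.
#' @export
intersect_entities <- function(assoc, mesh, seqs) {
  mirnas <- sort(intersect(unique(assoc$mirna), unique(seqs$mirna)))
  diseases <- sort(intersect(unique(assoc$disease), unique(mesh$disease)))
  dropped_m <- setdiff(unique(assoc$mirna), mirnas)
  dropped_d <- setdiff(unique(assoc$disease), diseases)
  if (length(dropped_m) || length(dropped_d)) {
    message(length(dropped_m), " miRNA(s) without sequence and ",
            length(dropped_d), " disease(s) without tree code dropped")
  }
  keep <- assoc$mirna %in% mirnas & assoc$disease %in% diseases
  out <- list(
    associations = assoc[keep, , drop = FALSE],
    mesh = mesh,
    sequences = seqs[seqs$mirna %in% mirnas, , drop = FALSE],
    mirnas = mirnas,
    diseases = diseases
  )
  rownames(out$associations) <- NULL
  class(out) <- "md_inputs"
  out
}
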