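# TSV dialect used throughout: tab-separated, header row, no quoting,
# missing values as empty string, booleans as "true"/"false", numerics at
# %.12g. Feature tables are features-as-rows with a leading "feature_id"
# column (classic OTU-table orientation).

.fmt_num <- function(x) {
  out <- ifelse(is.na(x), "", sprintf("%.12g", x))
  out
}

.write_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    col <- df2[[j]]
    if (is.logical(col)) {
      df2[[j]] <- ifelse(is.na(col), "", ifelse(col, "true", "false"))
    } else if (is.numeric(col)) {
      df2[[j]] <- .fmt_num(col)
    } else {
      col <- as.character(col)
      df2[[j]] <- ifelse(is.na(col), "", col)
    }
  }
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "",
                    colClasses = NA)
}

.as_logical_col <- function(x) {
  if (is.logical(x)) return(x)
  out <- rep(NA, length(x))
  out[x %in% c("true", "TRUE", "True")] <- TRUE
  out[x %in% c("false", "FALSE", "False")] <- FALSE
  out
}

#' Write a feature table to TSV
#' @param ft A [feature_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  df <- data.frame(feature_id = ft$feature_ids, ft$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Read a feature table from TSV
#' @param path TSV file with a `feature_id` column and one column per sample.
#' @param dataset_label `"DNA"` or `"RNA"`.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, dataset_label) {
  df <- .read_tsv(path)
  if (names(df)[1] != "feature_id")
    stop("feature table ", path, " must start with a feature_id column")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$feature_id)
  feature_table(m, dataset_label)
}

.metadata_cols <- c("sample_id", "group", "farm_id", "x_km", "y_km", "sex",
                    "weight", "body_length", "tail_length", "pregnancy",
                    "conc_dna", "conc_rna", "is_negative_control")

#' Read sample metadata from TSV
#' @param path TSV with columns `sample_id, group, farm_id, x_km, y_km, sex,
#'   weight, body_length, tail_length, pregnancy, conc_dna, conc_rna,
#'   is_negative_control`.
#' @return A data.frame with typed columns.
#' @export
read_metadata <- function(path) {
  df <- .read_tsv(path)
  missing <- setdiff(c("sample_id", "group"), names(df))
  if (length(missing))
    stop("metadata ", path, " lacks required columns: ",
         paste(missing, collapse = ","))
  for (cc in setdiff(.metadata_cols, names(df))) df[[cc]] <- NA
  for (cc in c("x_km", "y_km", "weight", "body_length", "tail_length",
               "conc_dna", "conc_rna"))
    df[[cc]] <- as.numeric(df[[cc]])
  for (cc in c("pregnancy", "is_negative_control"))
    df[[cc]] <- .as_logical_col(df[[cc]])
  df$sample_id <- as.character(df$sample_id)
  df[, .metadata_cols]
}

#' Write sample metadata to TSV
#' @param md Metadata data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(md, path) {
  for (cc in setdiff(.metadata_cols, names(md))) md[[cc]] <- NA
  .write_tsv(md[, .metadata_cols], path)
}

#' Read a taxonomy table (feature_id, phylum..genus) from TSV
#' @param path TSV path.
#' @return data.frame with columns feature_id, phylum, class, order, family,
#'   genus; empty ranks become "Unclassified".
#' @export
read_taxonomy <- function(path) {
  df <- .read_tsv(path)
  ranks <- c("phylum", "class", "order", "family", "genus")
  for (r in ranks) {
    if (is.null(df[[r]])) df[[r]] <- "Unclassified"
    df[[r]][is.na(df[[r]])] <- "Unclassified"
  }
  df$feature_id <- as.character(df$feature_id)
  df[, c("feature_id", ranks)]
}

#' Write a taxonomy table to TSV
#' @param tax Taxonomy data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) .write_tsv(tax, path)

#' Read an aligned or unaligned FASTA file as a sequence_set
#' @param path FASTA path.
#' @param aligned Logical.
#' @return A [sequence_set()].
#' @export
read_fasta_set <- function(path, aligned = FALSE) {
  x <- Biostrings::readDNAStringSet(path)
  sequence_set(stats::setNames(as.character(x), names(x)), aligned = aligned)
}

#' Write a sequence_set to FASTA
#' @param seqs A [sequence_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_set <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unclass(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a genotype table from TSV
#'
#' Wide format: column `individual_id`, then one column per locus with
#' cells "a/b" (two integer allele sizes) or empty for missing.
#' @param path TSV path.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path) {
  df <- .read_tsv(path)
  loci <- setdiff(names(df), "individual_id")
  n <- nrow(df)
  a1 <- a2 <- matrix(NA_integer_, n, length(loci),
                     dimnames = list(as.character(df$individual_id), loci))
  for (j in seq_along(loci)) {
    cell <- as.character(df[[loci[j]]])
    ok <- !is.na(cell) & nzchar(cell)
    parts <- strsplit(cell[ok], "/", fixed = TRUE)
    a1[ok, j] <- as.integer(vapply(parts, `[`, "", 1L))
    a2[ok, j] <- as.integer(vapply(parts, `[`, "", 2L))
  }
  genotype_table(a1, a2)
}

#' Write a genotype table to TSV
#' @param gt A [genotype_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path) {
  cells <- matrix("", length(gt$individual_ids), length(gt$locus_ids))
  ok <- !is.na(gt$a1)
  cells[ok] <- paste0(gt$a1[ok], "/", gt$a2[ok])
  df <- data.frame(individual_id = gt$individual_ids, cells,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("individual_id", gt$locus_ids)
  .write_tsv(df, path)
}

# TOML-flavoured key=value config reader: ignores blank lines, comments and
# [section] headers; values parsed as number, true/false, or bare string;
# comma-separated values become vectors; "name:value" pairs become named.
#' Read a key=value configuration file
#' @param path Config file path.
#' @return Named list of parsed values.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    val <- gsub('^"|"$', "", val)
    items <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    parse1 <- function(s) {
      if (grepl("^-?[0-9.eE+]+$", s) && !is.na(suppressWarnings(as.numeric(s))))
        return(as.numeric(s))
      if (s %in% c("true", "false")) return(s == "true")
      s
    }
    if (all(grepl(":", items, fixed = TRUE))) {
      pieces <- strsplit(items, ":", fixed = TRUE)
      vals <- unlist(lapply(pieces, function(p) parse1(trimws(p[2]))))
      out[[key]] <- stats::setNames(vals, vapply(pieces, function(p) trimws(p[1]), ""))
    } else if (length(items) > 1) {
      out[[key]] <- unlist(lapply(items, parse1))
    } else {
      out[[key]] <- parse1(items)
    }
  }
  out
}
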