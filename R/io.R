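# Readers and writers for every external table the pipeline touches.
# All gene symbols are uppercased on ingestion so that expression,
# interactome and gene-set sources match case-insensitively.

#' Read a probes-by-samples expression matrix
#'
#' Reads a tab-separated expression table whose first column holds probe
#' identifiers and whose header row holds sample identifiers. Preamble
#' lines starting with `!` (as found in GEO series-matrix exports) are
#' ignored, so both hand-made tables and GEO downloads parse.
#'
#' @param path Path to the delimited text file.
#' @param delimiter Field separator, default tab.
#' @return A numeric matrix (probes x samples) with probe ids as row
#'   names and sample ids as column names. All values are finite.
#' @examples
#' f <- tempfile()
#' writeLines(c("probe\ts1\ts2", "P1\t1\t2", "P2\t3\t4"), f)
#' read_expression_matrix(f)
#' @export
read_expression_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) {
    stop("expression file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) {
    stop("expression file has a header but no data rows: ", path, call. = FALSE)
  }
  dt <- data.table::fread(
    text = lines, sep = delimiter, header = TRUE,
    colClasses = "character", data.table = FALSE, na.strings = NULL
  )
  probes <- as.character(dt[[1]])
  dup <- unique(probes[duplicated(probes)])
  if (length(dup) > 0) {
    stop("duplicate probe id(s) in expression matrix: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  samples <- colnames(dt)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id(s) in expression matrix header", call. = FALSE)
  }
  if (length(samples) < 2) {
    stop("expression matrix must contain at least 2 samples", call. = FALSE)
  }
  values <- matrix(NA_real_, nrow = length(probes), ncol = length(samples),
                   dimnames = list(probes, samples))
  for (j in seq_along(samples)) {
    raw <- dt[[j + 1L]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) | !is.finite(num))
    if (length(bad) > 0) {
      stop(sprintf(
        "non-numeric or non-finite value '%s' at probe '%s', sample '%s'",
        raw[bad[1]], probes[bad[1]], samples[j]), call. = FALSE)
    }
    values[, j] <- num
  }
  values
}

#' Write an expression matrix as a tab-separated table
#'
#' Inverse of [read_expression_matrix()]: first column `probe_id`,
#' remaining columns one per sample.
#'
#' @param mat Numeric matrix with probe row names and sample column names.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  out <- data.table::data.table(probe_id = rownames(mat))
  out <- cbind(out, data.table::as.data.table(mat))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a sample-to-group assignment table
#'
#' Expects a two-column tab-separated file (`sample_id`, `group`), one
#' row per sample.
#'
#' @param path Path to the table.
#' @return Named character vector mapping sample id to group label.
#' @export
read_sample_groups <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = FALSE)
  if (ncol(dt) < 2) {
    stop("sample-group table needs columns: sample_id, group", call. = FALSE)
  }
  ids <- dt[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate sample id(s) in group table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(dt[[2]], ids)
}

#' Validate group labels against an expression matrix
#'
#' Checks that every sample carries exactly one label and that every
#' group is non-empty; at least two distinct groups are required.
#'
#' @param groups Named character vector (sample id -> group label).
#' @param sample_ids Sample ids that must all be labelled.
#' @return `groups` restricted to `sample_ids`, invisibly usable downstream.
#' @export
validate_sample_groups <- function(groups, sample_ids) {
  missing <- setdiff(sample_ids, names(groups))
  if (length(missing) > 0) {
    stop("samples without a group label: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  g <- groups[sample_ids]
  if (length(unique(g)) < 2) {
    stop("need at least 2 distinct group labels", call. = FALSE)
  }
  g
}

#' Read a probe-to-gene-symbol annotation table
#'
#' Two-column tab-separated table (`probe_id`, `symbol`). Symbols are
#' uppercased; an empty or missing symbol marks an unannotated probe.
#'
#' @param path Path to the table.
#' @return Named character vector probe id -> symbol ("" when absent).
#' @export
read_probe_annotation <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = FALSE,
                          na.strings = NULL)
  if (ncol(dt) < 2) {
    stop("annotation table needs columns: probe_id, symbol", call. = FALSE)
  }
  probes <- dt[[1]]
  if (anyDuplicated(probes)) {
    stop("duplicate probe id(s) in annotation: ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "),
         call. = FALSE)
  }
  sym <- toupper(trimws(dt[[2]]))
  sym[is.na(sym)] <- ""
  stats::setNames(sym, probes)
}

#' Translate probe ids to unique gene symbols
#'
#' Probes with no annotation entry or an empty symbol are dropped;
#' duplicate symbols collapse to their first appearance, preserving
#' input order. A probe id absent from the annotation is treated like
#' an unannotated probe (annotation gaps are expected, not errors).
#'
#' @param probes Character vector of probe ids.
#' @param annotation Named character vector from [read_probe_annotation()].
#' @return Character vector of unique gene symbols in first-appearance order.
#' @examples
#' map_probes_to_genes(c("p1", "p2", "p3"),
#'                     c(p1 = "TP53", p2 = "TP53", p3 = ""))
#' @export
map_probes_to_genes <- function(probes, annotation) {
  if (length(probes) == 0) return(character(0))
  sym <- unname(annotation[probes])
  sym[is.na(sym)] <- ""
  unique(sym[nzchar(sym)])
}

# default BioGRID TAB column names; configurable in read_interactions
biogrid_default_columns <- function() {
  list(symbol_a = "Official Symbol Interactor A",
       symbol_b = "Official Symbol Interactor B",
       system_type = "Experimental System Type",
       organism_a = "Organism Interactor A",
       organism_b = "Organism Interactor B")
}

#' Read a BioGRID-style interaction table
#'
#' Parses a tab-separated interaction file exposing interactor symbols,
#' organism taxon ids and the experimental system type. Column names
#' default to the BioGRID TAB dialect and are configurable. Rows missing
#' either interactor symbol are skipped; the skip count is reported via
#' `message()` and attached as attribute `"skipped"`.
#'
#' @param path Path to the interaction table.
#' @param columns Named list overriding any of `symbol_a`, `symbol_b`,
#'   `system_type`, `organism_a`, `organism_b` column names.
#' @return A data.frame with columns `symbol_a`, `symbol_b`,
#'   `organism_a`, `organism_b` (integer taxon ids) and `system_type`
#'   (`"physical"` or `"genetic"`), one row per retained input row, with
#'   attribute `"skipped"` (number of rows dropped for missing symbols).
#' @export
read_interactions <- function(path, columns = list()) {
  cols <- utils::modifyList(biogrid_default_columns(), columns)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = FALSE,
                          na.strings = NULL)
  missing <- setdiff(unlist(cols), colnames(dt))
  if (length(missing) > 0) {
    stop("interaction file lacks expected column(s): ",
         paste(missing, collapse = ", "),
         "; found: ", paste(colnames(dt), collapse = ", "), call. = FALSE)
  }
  a <- toupper(trimws(dt[[cols$symbol_a]]))
  b <- toupper(trimws(dt[[cols$symbol_b]]))
  keep <- nzchar(a) & nzchar(b) & !is.na(a) & !is.na(b) & a != "-" & b != "-"
  skipped <- sum(!keep)
  if (skipped > 0) {
    message("read_interactions: skipped ", skipped,
            " row(s) with a missing interactor symbol")
  }
  rec <- data.frame(
    symbol_a = a[keep],
    symbol_b = b[keep],
    organism_a = as.integer(dt[[cols$organism_a]][keep]),
    organism_b = as.integer(dt[[cols$organism_b]][keep]),
    system_type = tolower(trimws(dt[[cols$system_type]][keep])),
    stringsAsFactors = FALSE
  )
  attr(rec, "skipped") <- skipped
  rec
}

#' Write interaction records in the BioGRID TAB dialect
#'
#' @param records Data.frame as returned by [read_interactions()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(records, path) {
  cols <- biogrid_default_columns()
  out <- data.table::data.table(
    a = records$symbol_a, b = records$symbol_b,
    st = records$system_type,
    oa = records$organism_a, ob = records$organism_b
  )
  data.table::setnames(out, c(cols$symbol_a, cols$symbol_b, cols$system_type,
                              cols$organism_a, cols$organism_b))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' Each line: set name, description, then one or more member symbols,
#' tab-separated. Member symbols are uppercased and deduplicated.
#'
#' @param path Path to the GMT file.
#' @return A named list of class `gene_set_collection`; each element is
#'   `list(description =, genes =)`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d ('%s') has no members: need name, description, >=1 gene",
                   i, fields[1]), call. = FALSE)
    }
    name <- fields[1]
    if (name %in% names(sets)) {
      stop("duplicate gene-set name: ", name, call. = FALSE)
    }
    genes <- unique(toupper(trimws(fields[-(1:2)])))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      stop(sprintf("gene set '%s' has only empty members", name), call. = FALSE)
    }
    sets[[name]] <- list(description = fields[2], genes = genes)
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection in GMT format
#'
#' @param sets A `gene_set_collection` (see [read_gene_sets()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, sets[[nm]]$description, sets[[nm]]$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a validated Ct table
#'
#' @param ct Numeric matrix of quantification cycles, genes x animals.
#' @param groups Named character vector animal id -> group label.
#' @param reference_genes Character vector of endogenous reference genes
#'   (must be rows of `ct`).
#' @return An object of class `ct_table`: `list(ct, groups, reference_genes)`.
#' @export
ct_table <- function(ct, groups, reference_genes) {
  stopifnot(is.matrix(ct), !is.null(rownames(ct)), !is.null(colnames(ct)))
  rownames(ct) <- toupper(rownames(ct))
  reference_genes <- toupper(reference_genes)
  if (length(reference_genes) < 1) {
    stop("at least one reference gene is required", call. = FALSE)
  }
  missing_ref <- setdiff(reference_genes, rownames(ct))
  if (length(missing_ref) > 0) {
    stop("reference gene(s) absent from the Ct table: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(ct) | ct <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-finite or non-positive Ct at gene '%s', animal '%s'",
                 rownames(ct)[bad[1, 1]], colnames(ct)[bad[1, 2]]),
         call. = FALSE)
  }
  missing_lab <- setdiff(colnames(ct), names(groups))
  if (length(missing_lab) > 0) {
    stop("animals without a group label: ",
         paste(missing_lab, collapse = ", "), call. = FALSE)
  }
  structure(list(ct = ct, groups = groups[colnames(ct)],
                 reference_genes = reference_genes),
            class = "ct_table")
}

#' Read a qPCR Ct table
#'
#' Tab-separated table: first column gene names, one column per animal.
#' One row (default id `group`) carries the group label of each animal
#' instead of Ct values. Reference genes are declared by the caller, not
#' in the file.
#'
#' @param path Path to the table.
#' @param reference_genes Character vector of reference gene names.
#' @param group_row Row identifier holding group labels (default "group").
#' @return A `ct_table` object.
#' @export
read_ct_table <- function(path, reference_genes, group_row = "group") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = FALSE,
                          na.strings = NULL)
  ids <- dt[[1]]
  gi <- which(tolower(ids) == tolower(group_row))
  if (length(gi) != 1) {
    stop("Ct table must contain exactly one '", group_row, "' row", call. = FALSE)
  }
  animals <- colnames(dt)[-1]
  groups <- stats::setNames(as.character(dt[gi, -1]), animals)
  genes <- ids[-gi]
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(dt[-gi, -1, drop = FALSE])),
           nrow = length(genes), dimnames = list(genes, animals))
  )
  ct_table(vals, groups, reference_genes)
}

#' Write a Ct table with its group-label row
#'
#' @param x A `ct_table` object.
#' @param path Output file path.
#' @param group_row Identifier for the group-label row.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path, group_row = "group") {
  header <- paste(c("gene", colnames(x$ct)), collapse = "\t")
  gline <- paste(c(group_row, unname(x$groups)), collapse = "\t")
  body <- vapply(seq_len(nrow(x$ct)), function(i) {
    paste(c(rownames(x$ct)[i],
            format(x$ct[i, ], digits = 15, trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, gline, body), path)
  invisible(path)
}
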