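#' Read an expression matrix (TSV or GCT 1.2)
#'
#' Plain TSV: a header row of sample names whose first column holds probe
#' IDs. GCT 1.2: a `#1.2` version line, a `rows<TAB>cols` dimension line,
#' then a header with `Name` and `Description` columns before the samples.
#' Probe order is file order; it is never changed on read.
#'
#' @param path file to read.
#' @param dialect `"tsv"` or `"gct"`.
#' @return numeric matrix, probes in rows (rownames), samples in columns
#'   (colnames).
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (dialect == "gct") {
    if (length(lines) < 3L || !identical(trimws(lines[1L]), "#1.2"))
      stop("malformed GCT header: first line must be '#1.2' in ", path)
    dims <- suppressWarnings(as.integer(strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]))
    if (length(dims) < 2L || anyNA(dims[1:2]))
      stop("malformed GCT dimensions line in ", path)
    body <- lines[-(1:2)]
    skip_desc <- TRUE
  } else {
    dims <- NULL
    body <- lines
    skip_desc <- FALSE
  }
  body <- body[nzchar(body)]
  if (length(body) < 2L) stop("malformed matrix file (no data rows): ", path)
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  n_meta <- if (skip_desc) 2L else 1L
  samples <- header[-seq_len(n_meta)]
  if (length(samples) < 1L) stop("malformed header: no sample columns in ", path)
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  nfield <- lengths(rows)
  expected <- n_meta + length(samples)
  if (any(nfield != expected))
    stop(sprintf("row %d has %d fields, expected %d, in %s",
                 which(nfield != expected)[1L] + 1L,
                 nfield[nfield != expected][1L], expected, path))
  if (!is.null(dims)) {
    if (length(rows) != dims[1L] || length(samples) != dims[2L])
      stop(sprintf(
        "GCT dimension mismatch: dims line says %d x %d, body has %d x %d",
        dims[1L], dims[2L], length(rows), length(samples)))
  }
  probes <- vapply(rows, `[[`, "", 1L)
  if (anyDuplicated(probes))
    stop("duplicate probe ID(s): ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "))
  cells <- vapply(rows, function(r) r[-seq_len(n_meta)],
                  character(length(samples)))
  cells <- matrix(cells, nrow = length(samples))  # samples x probes
  vals <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(vals) & !(trimws(cells) %in% c("NA", "")))
  if (length(bad)) {
    b <- bad[1L] - 1L
    stop(sprintf("non-numeric value '%s' at data row %d, sample column %d in %s",
                 cells[bad[1L]], b %/% length(samples) + 1L,
                 b %% length(samples) + 1L, path))
  }
  m <- t(matrix(vals, nrow = length(samples), ncol = length(rows)))
  dimnames(m) <- list(probes, samples)
  m
}

#' Write an expression matrix
#'
#' @param values numeric matrix with probe rownames and sample colnames.
#' @param path destination file.
#' @param dialect `"tsv"` (default) or `"gct"` (version 1.2).
#' @export
write_expression_matrix <- function(values, path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  con <- file(path, open = "wb")  # binary: force LF on every platform
  on.exit(close(con))
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  if (dialect == "gct") {
    writeLines(c("#1.2", paste(nrow(values), ncol(values), sep = "\t")), con)
    writeLines(paste(c("Name", "Description", colnames(values)),
                     collapse = "\t"), con)
    body <- vapply(seq_len(nrow(values)), function(i)
      paste(c(rownames(values)[i], "na", fmt(values[i, ])), collapse = "\t"),
      "")
  } else {
    writeLines(paste(c("probe_id", colnames(values)), collapse = "\t"), con)
    body <- vapply(seq_len(nrow(values)), function(i)
      paste(c(rownames(values)[i], fmt(values[i, ])), collapse = "\t"), "")
  }
  writeLines(body, con)
  invisible(path)
}

#' Read per-sample class labels
#'
#' Two-column tab-delimited file with header `sample<TAB>class`; classes must
#' be `treatment` or `control`. When `samples` is given, labels are returned
#' aligned to that order (the file may list samples in any order).
#'
#' @param path label file.
#' @param samples optional character vector of sample names to align to.
#' @return named character vector of classes.
#' @export
read_class_labels <- function(path, samples = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (ncol(df) < 2L || !all(c("sample", "class") %in% names(df)))
    stop("label file needs columns 'sample' and 'class': ", path)
  bad <- setdiff(unique(df$class), c("treatment", "control"))
  if (length(bad))
    stop("unknown class token(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$sample))
    stop("duplicate sample name(s) in label file: ", path)
  labels <- stats::setNames(df$class, df$sample)
  if (!is.null(samples)) {
    missing <- setdiff(samples, names(labels))
    if (length(missing))
      stop("sample(s) missing from label file: ",
           paste(missing, collapse = ", "))
    labels <- labels[samples]
  }
  labels
}

#' @rdname read_class_labels
#' @param labels named character vector (names = samples) to write.
#' @export
write_class_labels <- function(labels, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("sample\tclass",
               paste(names(labels), labels, sep = "\t")), con)
  invisible(path)
}

#' Read/write a response signature in GMT dialect
#'
#' One line per direction, named `<id>_up` / `<id>_down`, with the method in
#' the description field and members in the remaining fields. An empty
#' direction is simply omitted on write and read back as the empty set.
#' Member order is not significant.
#'
#' @param sig a [response_signature()].
#' @param path file path.
#' @return `read_signature` returns a [response_signature()].
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "response_signature"))
  if (!length(sig$up) && !length(sig$down))
    stop("refusing to write an empty signature (no up and no down probes)")
  con <- file(path, open = "wb")
  on.exit(close(con))
  out <- character(0)
  if (length(sig$up))
    out <- c(out, paste(c(paste0(sig$perturbagen_id, "_up"), sig$method,
                          sig$up), collapse = "\t"))
  if (length(sig$down))
    out <- c(out, paste(c(paste0(sig$perturbagen_id, "_down"), sig$method,
                          sig$down), collapse = "\t"))
  writeLines(out, con)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty signature file: ", path)
  up <- character(0); down <- character(0)
  id <- NULL; method <- "fold_change"
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line with fewer than 3 fields in ", path)
    name <- f[1L]
    if (grepl("_up$", name)) {
      up <- f[-(1:2)]
      this_id <- sub("_up$", "", name)
    } else if (grepl("_down$", name)) {
      down <- f[-(1:2)]
      this_id <- sub("_down$", "", name)
    } else {
      stop("GMT set name must end in '_up' or '_down': ", name)
    }
    if (!is.null(id) && !identical(id, this_id))
      stop("signature file mixes perturbagens: ", id, " vs ", this_id)
    id <- this_id
    method <- f[2L]
  }
  if (!method %in% c("fold_change", "sam", "amplitude", "permuted", "planted"))
    method <- "fold_change"
  response_signature(id, up = up, down = down, method = method)
}

#' Read/write a ranked response pattern in RNK dialect
#'
#' Two tab-separated columns (probe, statistic), no header, one probe per
#' line in rank order (most up-regulated first). The reader validates the
#' ordering rather than silently re-sorting.
#'
#' @param pattern a [ranked_pattern()].
#' @param path file path.
#' @export
write_rnk <- function(pattern, path) {
  stopifnot(inherits(pattern, "ranked_pattern"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(pattern$probe_ids,
                   formatC(pattern$stat, format = "g", digits = 17),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_rnk
#' @export
read_rnk <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = c("character", "numeric"))
  if (ncol(df) != 2L) stop("RNK file must have exactly 2 columns: ", path)
  ranked_pattern(df[[1L]], df[[2L]], sort = FALSE)
}

#' Read/write a perturbagen catalogue
#'
#' Tab-delimited with header; required columns `perturbagen_id`, `kind`
#' (`miRNA`/`small_molecule`), `condition`, `source_id`; optional columns
#' (`fda_approved`, structure strings, ATC codes, external IDs) pass through
#' untouched. `(perturbagen_id, condition, source_id)` triples must be
#' unique.
#'
#' @param path file path.
#' @param catalogue data frame to write.
#' @return `read_catalogue` returns a data frame.
#' @export
read_catalogue <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  validate_catalogue(df)
}

#' @rdname read_catalogue
#' @export
write_catalogue <- function(catalogue, path) {
  validate_catalogue(catalogue)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(catalogue), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(catalogue, as.character), sep = "\t")),
             con)
  invisible(path)
}

validate_catalogue <- function(df) {
  need <- c("perturbagen_id", "kind", "condition", "source_id")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("catalogue missing column(s): ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(df$kind), c("miRNA", "small_molecule"))
  if (length(bad))
    stop("unknown perturbagen kind(s): ", paste(bad, collapse = ", "))
  key <- paste(df$perturbagen_id, df$condition, df$source_id, sep = "\x1f")
  if (anyDuplicated(key))
    stop("duplicate (perturbagen_id, condition, source_id) triple(s) in catalogue")
  df
}

#' Enumerate candidate molecule-by-miRNA-profile pairs
#'
#' Every distinct small molecule is paired with every miRNA profile (one row
#' per miRNA catalogue entry: the same miRNA transfected under different
#' conditions counts as separate profiles).
#'
#' @param catalogue a catalogue data frame (see [read_catalogue()]).
#' @return data frame with columns `molecule_id`, `mirna_profile_id`.
#' @export
candidate_pairs <- function(catalogue) {
  catalogue <- validate_catalogue(catalogue)
  molecules <- unique(catalogue$perturbagen_id[catalogue$kind == "small_molecule"])
  mir <- catalogue[catalogue$kind == "miRNA", , drop = FALSE]
  mirna_profiles <- paste(mir$perturbagen_id, mir$condition, mir$source_id,
                          sep = "|")
  if (!length(molecules) || !length(mirna_profiles))
    return(data.frame(molecule_id = character(0),
                      mirna_profile_id = character(0)))
  data.frame(
    molecule_id = rep(molecules, times = length(mirna_profiles)),
    mirna_profile_id = rep(mirna_profiles, each = length(molecules)),
    stringsAsFactors = FALSE)
}

#' Write/read an association table
#'
#' Tab-delimited with header `small_molecule`, `fda_approved`, `mirna`,
#' `source_id`, `condition`, `AS`, `p_value`, `n_instances`, plus any extra
#' annotation columns present in `records`. `AS` is printed with 6 decimals.
#' Comment lines beginning `#` (tool version, config hash, seed) are written
#' before the header and skipped on read.
#'
#' @param records data frame of association records.
#' @param path destination.
#' @param comments optional character vector written as `# `-prefixed lines.
#' @export
write_association_table <- function(records, path, comments = NULL) {
  core <- c("small_molecule", "fda_approved", "mirna", "source_id",
            "condition", "AS", "p_value", "n_instances")
  missing <- setdiff(core, names(records))
  if (length(missing))
    stop("association records missing column(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(records), core)
  records <- records[, c(core, extra), drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(names(records), collapse = "\t"), con)
  if (nrow(records)) {
    cols <- lapply(names(records), function(nm) {
      x <- records[[nm]]
      if (nm %in% c("AS", "p_value")) sprintf("%.6f", x)
      else if (is.double(x)) formatC(x, format = "g", digits = 17)
      else as.character(x)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' @rdname write_association_table
#' @export
read_association_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", colClasses = "character")
  for (nm in intersect(c("AS", "p_value"), names(df)))
    df[[nm]] <- as.numeric(df[[nm]])
  if ("n_instances" %in% names(df))
    df$n_instances <- as.integer(df$n_instances)
  if ("fda_approved" %in% names(df))
    df$fda_approved <- as.logical(df$fda_approved)
  df
}
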