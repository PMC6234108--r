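#' The 14 retained molecular descriptors
#'
#' The fixed descriptor set used by the final bioconcentration models:
#' 6 topological indices (radial centric information index `ICR`, Narumi
#' harmonic topological index `HNar`, ramification index `Ram`,
#' superpendentic index `SPI`, spanning tree number `STN`, topological polar
#' surface area `TPSA`), 4 constitutional descriptors (atom counts `nH`,
#' `nC`, `nN` and molecular weight `MW`), 3 electrotopological descriptors
#' (`MAXDN`, `MAXDP`, mean Sanderson electronegativity `Me`) and 1
#' physico-chemical property (the octanol-water distribution coefficient
#' `logD`).
#'
#' @return Character vector of 14 descriptor names with a `"group"`
#'   attribute (a named factor assigning each descriptor to its class).
#' @examples
#' final_descriptor_set()
#' table(attr(final_descriptor_set(), "group"))
#' @export
final_descriptor_set <- function() {
  names <- c("ICR", "HNar", "Ram", "SPI", "STN", "TPSA",
             "nH", "nC", "nN", "MW",
             "MAXDN", "MAXDP", "Me",
             "logD")
  group <- factor(
    rep(c("topological", "constitutional", "electrotopological",
          "physicochemical"),
        times = c(6, 4, 3, 1)),
    levels = c("topological", "constitutional", "electrotopological",
               "physicochemical")
  )
  names(group) <- names
  structure(names, group = group)
}

new_descriptor_table <- function(ids, X, logbcf = NULL, smiles = NULL,
                                 meta = list(logd_ph = 7)) {
  stopifnot(is.matrix(X), is.numeric(X))
  rownames(X) <- ids
  structure(
    list(ids = as.character(ids), X = X, logbcf = logbcf, smiles = smiles,
         meta = meta),
    class = "descriptor_table"
  )
}

#' Construct a descriptor table
#'
#' Builds the pipeline's universal data container from a data frame: one
#' compound-identifier column, any number of numeric molecular-descriptor
#' columns, and optionally a SMILES column and a logBCF target column.
#'
#' @param x A data frame.
#' @param id_col Name of the compound-identifier column (default
#'   `"compound_id"`).
#' @param target_col Name of the logBCF column, if present (default
#'   `"logBCF"`). logBCF is the log10 of the bioconcentration factor in
#'   L/kg.
#' @param smiles_col Optional name of a SMILES column, carried as an opaque
#'   annotation.
#' @param logd_ph pH at which logD was computed; stored as metadata
#'   (default 7).
#' @param strict If `TRUE` (default), non-finite descriptor cells are an
#'   error; if `FALSE`, offending rows are dropped with a warning.
#' @return A `descriptor_table` with fields `ids`, `X` (numeric matrix,
#'   compounds x descriptors), `logbcf`, `smiles` and `meta`.
#' @export
descriptor_table <- function(x, id_col = "compound_id", target_col = "logBCF",
                             smiles_col = NULL, logd_ph = 7, strict = TRUE) {
  stopifnot(is.data.frame(x))
  if (!id_col %in% names(x)) {
    stop("format error: id column '", id_col, "' not found", call. = FALSE)
  }
  ids <- as.character(x[[id_col]])
  if (anyDuplicated(ids)) {
    stop("validation error: duplicate compound ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  smiles <- NULL
  if (!is.null(smiles_col)) {
    if (!smiles_col %in% names(x)) {
      stop("format error: smiles column '", smiles_col, "' not found",
           call. = FALSE)
    }
    smiles <- as.character(x[[smiles_col]])
  }
  desc_cols <- setdiff(names(x), c(id_col, target_col, smiles_col))
  if (length(desc_cols) == 0L) {
    stop("validation error: no descriptor columns", call. = FALSE)
  }
  bad_type <- desc_cols[!vapply(x[desc_cols], is.numeric, logical(1))]
  if (length(bad_type)) {
    stop("format error: non-numeric descriptor column(s): ",
         paste(bad_type, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(x[desc_cols])
  storage.mode(X) <- "double"

  logbcf <- NULL
  if (target_col %in% names(x)) {
    logbcf <- as.numeric(x[[target_col]])
  }

  bad_row <- rowSums(!is.finite(X)) > 0
  if (!is.null(logbcf)) bad_row <- bad_row | !is.finite(logbcf)
  if (any(bad_row)) {
    if (strict) {
      stop("validation error: non-finite values in rows: ",
           paste(ids[bad_row], collapse = ", "),
           " (use strict = FALSE to drop them)", call. = FALSE)
    }
    warning(sum(bad_row), " row(s) with non-finite values dropped: ",
            paste(ids[bad_row], collapse = ", "), call. = FALSE)
    keep <- !bad_row
    ids <- ids[keep]
    X <- X[keep, , drop = FALSE]
    if (!is.null(logbcf)) logbcf <- logbcf[keep]
    if (!is.null(smiles)) smiles <- smiles[keep]
  }
  if (!is.null(logbcf)) names(logbcf) <- ids
  new_descriptor_table(ids, X, logbcf, smiles, meta = list(logd_ph = logd_ph))
}

#' Read a descriptor table from delimited text
#'
#' Reads a CSV/TSV file with a header row into a [descriptor_table()].
#' Leading comment lines of the form `# key=value` are parsed as sidecar
#' metadata (e.g. `# logd_ph=7`).
#'
#' @param path Path to the file.
#' @param sep Field delimiter (default `","`).
#' @inheritParams descriptor_table
#' @return A `descriptor_table`.
#' @export
read_descriptor_table <- function(path, sep = ",", id_col = "compound_id",
                                  target_col = "logBCF", smiles_col = NULL,
                                  strict = TRUE) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  meta <- list(logd_ph = 7)
  is_meta <- grepl("^#", lines)
  header_meta <- lines[seq_len(match(FALSE, is_meta, nomatch = 0L) - 1L)]
  for (ln in header_meta) {
    kv <- sub("^#\\s*", "", ln)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- trimws(sub("=.*", "", kv))
      val <- trimws(sub("^[^=]*=", "", kv))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  df <- utils::read.table(text = lines, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  tbl <- descriptor_table(df, id_col = id_col, target_col = target_col,
                          smiles_col = smiles_col,
                          logd_ph = meta$logd_ph, strict = strict)
  tbl$meta <- utils::modifyList(tbl$meta, meta)
  tbl
}

#' Write a descriptor table to delimited text
#'
#' Inverse of [read_descriptor_table()]; metadata is written as leading
#' `# key=value` comment lines.
#'
#' @param table A `descriptor_table`.
#' @param path Output file path.
#' @param sep Field delimiter.
#' @export
write_descriptor_table <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "descriptor_table"))
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(table$meta)) {
    writeLines(sprintf("# %s=%s", key, table$meta[[key]]), con)
  }
  utils::write.table(as.data.frame(table), con, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.descriptor_table <- function(x, ...) {
  df <- data.frame(compound_id = x$ids, stringsAsFactors = FALSE)
  if (!is.null(x$smiles)) df$smiles <- x$smiles
  df <- cbind(df, as.data.frame(x$X, row.names = seq_along(x$ids)))
  if (!is.null(x$logbcf)) df$logBCF <- unname(x$logbcf)
  df
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat("descriptor_table:", length(x$ids), "compounds x", ncol(x$X),
      "descriptors;",
      if (is.null(x$logbcf)) "no logBCF target" else "logBCF target present",
      "\n")
  cat("descriptors:", paste(utils::head(colnames(x$X), 8), collapse = ", "),
      if (ncol(x$X) > 8) "..." else "", "\n")
  invisible(x)
}

#' Number of compounds / descriptor names
#'
#' @param table A `descriptor_table`.
#' @return `n_compounds()` the row count; `descriptor_names()` the column
#'   names of the descriptor matrix.
#' @export
n_compounds <- function(table) length(table$ids)

#' @rdname n_compounds
#' @export
descriptor_names <- function(table) colnames(table$X)

#' Subset a descriptor table
#'
#' `subset_rows()` keeps the given compounds (by id), `subset_descriptors()`
#' keeps the given descriptor columns, preserving all other fields.
#'
#' @param table A `descriptor_table`.
#' @param ids Compound ids to keep (order respected).
#' @param names Descriptor names to keep (order respected).
#' @export
subset_rows <- function(table, ids) {
  stopifnot(inherits(table, "descriptor_table"))
  idx <- match(ids, table$ids)
  if (anyNA(idx)) {
    stop("unknown compound id(s): ", paste(ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  new_descriptor_table(table$ids[idx], table$X[idx, , drop = FALSE],
                       if (!is.null(table$logbcf)) table$logbcf[idx],
                       if (!is.null(table$smiles)) table$smiles[idx],
                       table$meta)
}

#' @rdname subset_rows
#' @export
subset_descriptors <- function(table, names) {
  stopifnot(inherits(table, "descriptor_table"))
  missing <- setdiff(names, colnames(table$X))
  if (length(missing)) {
    stop("schema error: descriptor(s) not in table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  new_descriptor_table(table$ids, table$X[, names, drop = FALSE],
                       table$logbcf, table$smiles, table$meta)
}

#' Remove degenerate descriptor columns
#'
#' Drops descriptor columns that have zero variance or contain any
#' non-finite value, mirroring the pre-processing applied to raw
#' descriptor dumps before modelling. Idempotent.
#'
#' @param table A `descriptor_table`.
#' @return The cleaned table, with an attribute `"removed"` listing the
#'   dropped columns (`$zero_variance`, `$non_finite`).
#' @export
clean_descriptors <- function(table) {
  stopifnot(inherits(table, "descriptor_table"))
  if (n_compounds(table) == 0L) stop("empty table", call. = FALSE)
  X <- table$X
  non_finite <- colnames(X)[colSums(!is.finite(X)) > 0]
  sds <- apply(X, 2, function(col) {
    col <- col[is.finite(col)]
    if (length(col) < 2) 0 else stats::sd(col)
  })
  zero_var <- setdiff(colnames(X)[sds == 0], non_finite)
  drop <- union(non_finite, zero_var)
  keep <- setdiff(colnames(X), drop)
  if (length(keep) == 0L) {
    stop("empty-feature error: all descriptor columns removed", call. = FALSE)
  }
  out <- subset_descriptors(table, keep)
  attr(out, "removed") <- list(zero_variance = zero_var,
                               non_finite = non_finite)
  out
}

#' Log-transform a bioconcentration factor
#'
#' @param bcf Bioconcentration factor(s) in L/kg; must be positive.
#' @return `log10(bcf)`.
#' @examples
#' log_transform_bcf(1000) # 3
#' @export
log_transform_bcf <- function(bcf) {
  if (!is.numeric(bcf) || any(!is.finite(bcf)) || any(bcf <= 0)) {
    stop("domain error: BCF must be positive and finite", call. = FALSE)
  }
  log10(bcf)
}

#' Split a table into training / verification / test subsets
#'
#' Simple random partition into three disjoint id sets with exactly the
#' requested sizes, reproducible for a fixed seed. The verification subset
#' plays the role of an internal validation set (bandwidth/architecture
#' selection, early stopping); the test subset is external validation.
#'
#' @param table A `descriptor_table`.
#' @param sizes Integer vector `c(train, verify, test)`; must sum to the
#'   number of compounds.
#' @param seed Integer seed.
#' @return A `split_assignment` with `train_ids`, `verify_ids`, `test_ids`
#'   and `seed`.
#' @export
split_dataset <- function(table, sizes, seed = 1L) {
  stopifnot(inherits(table, "descriptor_table"))
  sizes <- as.integer(sizes)
  if (length(sizes) != 3L || any(sizes < 0L)) {
    stop("sizes must be three non-negative counts", call. = FALSE)
  }
  n <- n_compounds(table)
  if (sum(sizes) != n) {
    stop("size error: counts sum to ", sum(sizes), " but table has ", n,
         " compounds", call. = FALSE)
  }
  set.seed(seed)
  perm <- sample(table$ids)
  structure(
    list(train_ids = perm[seq_len(sizes[1])],
         verify_ids = perm[sizes[1] + seq_len(sizes[2])],
         test_ids = perm[sizes[1] + sizes[2] + seq_len(sizes[3])],
         seed = as.integer(seed)),
    class = "split_assignment"
  )
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("split_assignment: train %d / verify %d / test %d (seed %d)\n",
              length(x$train_ids), length(x$verify_ids), length(x$test_ids),
              x$seed))
  invisible(x)
}

#' Default train/verify/test counts from fractions
#'
#' Computes split counts from verification/test fractions by rounding each
#' down and assigning the remainder to training.
#'
#' @param n Total number of compounds.
#' @param verify_frac,test_frac Fractions for verification and test.
#' @return Integer vector `c(train, verify, test)`.
#' @export
default_split_sizes <- function(n, verify_frac = 0.15, test_frac = 0.15) {
  stopifnot(n >= 0, verify_frac >= 0, test_frac >= 0,
            verify_frac + test_frac <= 1)
  v <- floor(n * verify_frac)
  t <- floor(n * test_frac)
  c(train = n - v - t, verify = v, test = t)
}

#' Centre and scale descriptors using training statistics
#'
#' Standardizes every descriptor column as `(x - mean) / sd` where mean and
#' sd are computed on the training rows only; verification and test rows
#' are transformed with the same training statistics.
#'
#' @param table A `descriptor_table`.
#' @param train_ids Ids of training rows used for the statistics; default
#'   all rows.
#' @return List with `table` (transformed) and `record` (list of `center`
#'   and `scale` named vectors, for inverse use).
#' @seealso [apply_standardization()], [invert_standardization()]
#' @export
standardize <- function(table, train_ids = NULL) {
  stopifnot(inherits(table, "descriptor_table"))
  if (is.null(train_ids)) train_ids <- table$ids
  tr <- subset_rows(table, train_ids)
  if (n_compounds(tr) < 2L) {
    stop("need at least 2 training rows", call. = FALSE)
  }
  center <- colMeans(tr$X)
  scale <- apply(tr$X, 2, stats::sd)
  if (any(scale == 0)) {
    stop("degenerate-feature error: zero training sd for ",
         paste(colnames(tr$X)[scale == 0], collapse = ", "),
         " (run clean_descriptors first)", call. = FALSE)
  }
  record <- list(center = center, scale = scale)
  list(table = apply_standardization(table, record), record = record)
}

#' Apply or invert a standardization record
#'
#' @param table A `descriptor_table`.
#' @param record A `list(center, scale)` as returned by [standardize()].
#' @export
apply_standardization <- function(table, record) {
  nm <- colnames(table$X)
  stopifnot(all(nm %in% names(record$center)))
  X <- sweep(table$X, 2, record$center[nm], "-")
  X <- sweep(X, 2, record$scale[nm], "/")
  out <- table
  out$X <- X
  out
}

#' @rdname apply_standardization
#' @export
invert_standardization <- function(table, record) {
  nm <- colnames(table$X)
  stopifnot(all(nm %in% names(record$center)))
  X <- sweep(table$X, 2, record$scale[nm], "*")
  X <- sweep(X, 2, record$center[nm], "+")
  out <- table
  out$X <- X
  out
}

#' Cases-to-descriptors (Topliss) ratio
#'
#' The ratio of training cases to model descriptors, a guard against chance
#' correlation; OECD QSAR guidance cites 5:1 as the minimum.
#'
#' @param n_train Number of training cases.
#' @param n_descriptors Number of descriptors (>= 1).
#' @return The ratio, with attribute `"label"` holding the nearest-integer
#'   `"k:1"` string.
#' @examples
#' topliss_ratio(242, 14) # ~17.3, "17:1"
#' @export
topliss_ratio <- function(n_train, n_descriptors) {
  if (n_descriptors < 1) {
    stop("domain error: n_descriptors must be >= 1", call. = FALSE)
  }
  ratio <- n_train / n_descriptors
  structure(ratio, label = topliss_label(ratio))
}

#' @rdname topliss_ratio
#' @param ratio A numeric ratio.
#' @export
topliss_label <- function(ratio) sprintf("%d:1", as.integer(round(ratio)))
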