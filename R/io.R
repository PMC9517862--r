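# Readers and writers for the derivative-table and activity-pair schemas.
# Tables are UTF-8 CSV with a header row; TSV is accepted. Unicode minus
# (U+2212), as printed in many toxicology tables, is normalized to ASCII
# hyphen-minus before parsing.

read_normalized <- function(path, sep = "auto") {
  if (!file.exists(path)) stop_schema("file not found: ", path)
  txt <- readLines(path, encoding = "UTF-8", warn = FALSE)
  txt <- gsub("−", "-", txt)
  if (identical(sep, "auto"))
    sep <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(text = txt, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE, quote = "\"",
                    blank.lines.skip = TRUE)
}

#' Read a derivative endpoint table
#'
#' Parses and validates a table of per-derivative toxicity and
#' environmental-behaviour endpoints. Mandatory columns are
#' \code{derivative_id}, \code{parent_acronym}, \code{pathway_id}, the three
#' binding-free-energy columns (\code{neuro_dg_kjmol},
#' \code{immuno_dg_kjmol}, \code{phyto_dg_kjmol}), \code{dev_prob},
#' \code{geno_prob}, \code{carc_active} and \code{endo_active};
#' \code{logbcf}, \code{half_life}, \code{persistence} and
#' \code{air_half_life} are optional. Empty cells are missing endpoints:
#' they are carried as \code{NA} and excluded from downstream statistics,
#' never imputed.
#'
#' Validated invariants: binding free energies finite and negative;
#' probabilities in \eqn{[0,1]}; activity calls in \{0, 1\}; times positive;
#' \code{pathway_id} in \code{\link{pah_pathways}} (plus
#' \code{extra_pathways}); \code{derivative_id} unique; and, when a
#' \code{registry} is supplied, every \code{parent_acronym} resolving.
#'
#' @param path file path (CSV, or TSV by extension/\code{sep}).
#' @param sep field separator; \code{"auto"} infers from the extension.
#' @param registry optional parent registry for reference checking.
#' @param extra_pathways additional pathway identifiers to accept beyond the
#'   controlled vocabulary.
#' @param on_invalid \code{"error"} (default) aborts naming the first
#'   offending row and column; \code{"skip"} drops invalid rows and counts
#'   them in the parse report.
#' @return A data.frame of class \code{derivative_table}, row order
#'   preserved, with a \code{parse_report} attribute
#'   (\code{list(n_rows, n_skipped)}).
#' @examples
#' cfg <- sim_config(seed = 1, n_per_pathway = 2,
#'                   pathways = c("photolysis", "human_metabolism"))
#' sim <- simulate_derivatives(cfg)
#' f <- tempfile(fileext = ".csv")
#' write_derivative_table(sim$derivatives, f)
#' nrow(read_derivative_table(f))
#' @export
read_derivative_table <- function(path, sep = c("auto", ",", "\t"),
                                  registry = NULL, extra_pathways = NULL,
                                  on_invalid = c("error", "skip")) {
  sep <- match.arg(sep)
  on_invalid <- match.arg(on_invalid)
  x <- read_normalized(path, sep)
  as_derivative_table(x, registry = registry, extra_pathways = extra_pathways,
                      on_invalid = on_invalid)
}

#' Validate a data.frame as a derivative table
#'
#' Same checks as \code{\link{read_derivative_table}} for in-memory data.
#'
#' @inheritParams read_derivative_table
#' @param x data.frame in the derivative-table schema.
#' @return validated \code{derivative_table}.
#' @export
as_derivative_table <- function(x, registry = NULL, extra_pathways = NULL,
                                on_invalid = c("error", "skip")) {
  on_invalid <- match.arg(on_invalid)
  miss <- setdiff(mandatory_columns(), names(x))
  if (length(miss))
    stop_schema("derivative table is missing mandatory column(s): ",
                paste(miss, collapse = ", "))

  num_cols <- intersect(c(mandatory_columns()[-(1:3)], optional_columns()),
                        names(x))
  for (col in num_cols) x[[col]] <- as.numeric(x[[col]])

  bad <- rep(FALSE, nrow(x))
  complain <- function(rows, msg) {
    if (!length(rows)) return(invisible())
    if (on_invalid == "error")
      stop_validation(sprintf("row %d: %s", rows[1], msg))
    bad[rows] <<- TRUE
  }

  ep <- pah_endpoints()
  for (i in seq_len(nrow(ep))) {
    col <- ep$column[i]
    if (!col %in% names(x)) next
    v <- x[[col]]
    ok <- is.na(v)
    rows <- switch(ep$scale[i],
      free_energy = which(!ok & (!is.finite(v) | v >= 0)),
      probability = which(!ok & (v < 0 | v > 1)),
      binary      = which(!ok & !(v %in% c(0, 1))),
      time        = which(!ok & (!is.finite(v) | v <= 0)),
      log10       = which(!ok & !is.finite(v)))
    complain(rows, sprintf(
      "%s = %s violates the %s invariant for endpoint '%s'",
      col, format(v[rows[1]]), ep$scale[i], ep$endpoint_id[i]))
  }

  vocab <- c(pah_pathways(), extra_pathways)
  complain(which(!x$pathway_id %in% vocab),
           sprintf("unknown pathway_id '%s'",
                   x$pathway_id[which(!x$pathway_id %in% vocab)[1]]))
  dup <- which(duplicated(x$derivative_id))
  complain(dup, sprintf("duplicate derivative_id '%s'",
                        x$derivative_id[dup[1]]))
  if (!is.null(registry))
    complain(which(!x$parent_acronym %in% registry$acronym),
             sprintf("parent_acronym '%s' not in the registry",
                     x$parent_acronym[which(!x$parent_acronym %in%
                                              registry$acronym)[1]]))

  n_total <- nrow(x)
  if (any(bad)) x <- x[!bad, , drop = FALSE]
  rownames(x) <- NULL
  structure(x, class = c("derivative_table", "data.frame"),
            parse_report = list(n_rows = nrow(x),
                                n_skipped = n_total - nrow(x)))
}

#' Write a derivative table
#'
#' Writes CSV (or TSV) preserving full double precision, so that
#' write-then-read is the identity on values and row order.
#'
#' @param x derivative table (or compatible data.frame).
#' @param path output path.
#' @param sep field separator.
#' @return the path, invisibly.
#' @export
write_derivative_table <- function(x, path, sep = c(",", "\t")) {
  sep <- match.arg(sep)
  write_table_precise(as.data.frame(x), path, sep = sep)
}

#' Read observed/predicted activity pairs
#'
#' Columns \code{molecule}, \code{observed}, \code{predicted}, \code{split}
#' (\code{training}/\code{test}); binding free energies in kJ/mol. Observed
#' values must be nonzero (relative error is undefined at zero).
#'
#' @param path file path.
#' @param sep field separator.
#' @return data.frame of activity pairs.
#' @export
read_activity_pairs <- function(path, sep = c("auto", ",", "\t")) {
  sep <- match.arg(sep)
  x <- read_normalized(path, sep)
  need <- c("molecule", "observed", "predicted", "split")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_schema("activity-pair table is missing column(s): ",
                paste(miss, collapse = ", "))
  x$observed <- as.numeric(x$observed)
  x$predicted <- as.numeric(x$predicted)
  if (any(x$observed == 0, na.rm = TRUE))
    stop_validation("observed value of 0 found; relative error undefined")
  if (!all(x$split %in% c("training", "test")))
    stop_validation("split must be 'training' or 'test'")
  x
}

REFERENCE_PAIRS_MD5 <- "3c8d594bf7e740e2a5b77a4ec9edc2e8"

#' Packaged reference activity pairs for the three QSAR models
#'
#' The experimental and predicted receptor-binding free energies (kJ/mol) of
#' the 23 PAHs used to build and validate the neurotoxicity (AHR),
#' immunotoxicity (p53) and phytotoxicity (peroxidase) QSAR models, together
#' with the published relative-error column (\code{rel_err_printed}, percent)
#' and the training/test split. 59 rows: 20 neurotoxicity (15 training, 5
#' test), 19 immunotoxicity (14 + 5), 20 phytotoxicity (15 + 5).
#'
#' @param model \code{"all"} or one of the three model names.
#' @return data.frame with columns \code{model}, \code{molecule},
#'   \code{split}, \code{observed}, \code{predicted},
#'   \code{rel_err_printed}.
#' @examples
#' head(qsar_reference_pairs("neurotoxicity"))
#' @export
qsar_reference_pairs <- function(model = c("all", "neurotoxicity",
                                           "immunotoxicity",
                                           "phytotoxicity")) {
  model <- match.arg(model)
  path <- system.file("extdata", "qsar_activity_pairs.csv",
                      package = "pahrisk", mustWork = TRUE)
  if (!identical(unname(tools::md5sum(path)), REFERENCE_PAIRS_MD5))
    stop_validation("packaged reference activity-pair fixture is corrupted ",
                    "(checksum mismatch)")
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (model != "all") x <- x[x$model == model, , drop = FALSE]
  rownames(x) <- NULL
  x
}
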