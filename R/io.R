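#' The bundled 57-compound CEC reference table
#'
#' Experimental profile of 57 reference drugs, all ionized at pH 7.4:
#' CEC retention factor k' (mean and SD of three runs), aqueous pKa, log P
#' and derived log D7.4 from automated potentiometric titration, literature
#' in vivo log BB, plus curator-provided charge (`positive`/`negative`) and
#' protolyte-kind annotations. Levofloxacin carries pKa 8.13 (its basic
#' group), the value used in the regression design matrix.
#'
#' @return Data frame of 57 validated compound records.
#' @examples
#' nrow(bbb_compounds())
#' @export
bbb_compounds <- function() {
  load_compound_table(system.file("extdata", "table1_compounds.csv",
                                  package = "cecbbb", mustWork = TRUE))
}

compound_numeric_cols <- c("k_prime", "k_prime_sd", "pka", "pka_sd",
                           "logp", "logp_sd", "logd74", "logbb")

#' Read and validate a compound table
#'
#' Expects a comma-separated file (comment lines starting with `#` allowed)
#' with columns `compound_id`, the numeric measurement columns `k_prime`,
#' `k_prime_sd`, `pka`, `pka_sd`, `logp`, `logp_sd`, `logd74`, `logbb`, and
#' the annotations `charge_kind`, `protolyte`. Errors name the offending
#' row and column.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
load_compound_table <- function(path) {
  d <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                colClasses = "character")
  need <- c("compound_id", compound_numeric_cols, "charge_kind", "protolyte")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_input("compound table is missing column(s): ",
               paste(miss, collapse = ", "))
  dup <- d$compound_id[duplicated(d$compound_id)]
  if (length(dup))
    stop_input("duplicate compound_id: ", paste(unique(dup), collapse = ", "))
  for (col in compound_numeric_cols) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop_input("non-numeric or missing '", col, "' in row(s) ",
                 paste(bad, collapse = ", "), " (",
                 paste(d$compound_id[bad], collapse = ", "), ")")
    d[[col]] <- v
  }
  badc <- which(!d$charge_kind %in% c("positive", "negative"))
  if (length(badc))
    stop_input("invalid charge_kind in row(s) ", paste(badc, collapse = ", "))
  d
}

#' @rdname load_compound_table
#' @param records Data frame to write.
#' @export
write_compound_table <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Load electropherogram traces from a manifest and trace directory
#'
#' The manifest (data frame or CSV path) needs columns `filename`,
#' `compound_id`, and either `class` or `logbb` (classes are then derived
#' with [label_from_logbb()]). Each trace file is a two-column CSV (time,
#' amplitude). Traces of unequal length are right-truncated to the common
#' minimum (`length_policy = "truncate"`) or linearly resampled to it
#' (`"resample"`).
#'
#' @param manifest Manifest data frame or CSV path.
#' @param directory Directory containing the trace files.
#' @param length_policy `"truncate"` or `"resample"`.
#' @return List with `traces` (raw amplitude matrix), `labels` and the
#'   augmented `manifest`.
#' @export
load_traces <- function(manifest, directory,
                        length_policy = c("truncate", "resample")) {
  length_policy <- match.arg(length_policy)
  if (is.character(manifest))
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("filename", "compound_id") %in% names(manifest)))
    stop_input("manifest needs 'filename' and 'compound_id' columns")
  if (!"class" %in% names(manifest)) {
    if (!"logbb" %in% names(manifest))
      stop_input("manifest needs a 'class' or 'logbb' column")
    manifest$class <- label_from_logbb(manifest$logbb)
  }
  sigs <- lapply(manifest$filename, function(f) {
    p <- file.path(directory, f)
    if (!file.exists(p)) stop_input("trace file not found: ", p)
    tr <- read.csv(p, stringsAsFactors = FALSE)
    if (nrow(tr) == 0L) stop_input("empty trace file: ", p)
    as.numeric(tr[[2]])
  })
  len <- min(lengths(sigs))
  sigs <- lapply(sigs, function(s) {
    if (length(s) == len) return(s)
    if (length_policy == "truncate") s[seq_len(len)]
    else approx(seq_along(s), s, n = len)$y
  })
  list(traces = do.call(rbind, sigs), labels = as.integer(manifest$class),
       manifest = manifest)
}

#' Write a simulated trace dataset as per-trace CSV files plus a manifest
#'
#' Produces the exact on-disk layout [load_traces()] reads: one two-column
#' (time, amplitude) CSV per trace and a `manifest.csv` with filename,
#' compound id, class and latent peak ground truth.
#'
#' @param dataset As returned by [simulate_dataset()].
#' @param directory Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_traces <- function(dataset, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  man <- dataset$manifest
  man$filename <- paste0(man$trace_id, ".csv")
  for (i in seq_len(nrow(man))) {
    tr <- data.frame(time = seq_len(ncol(dataset$traces)),
                     amplitude = dataset$traces[i, ])
    write.csv(tr, file.path(directory, man$filename[i]), row.names = FALSE)
  }
  path <- file.path(directory, "manifest.csv")
  write.csv(man, path, row.names = FALSE)
  invisible(path)
}
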