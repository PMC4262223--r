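#' Read one sample's event matrix
#'
#' Reads a delimited text file (header row of channel names, one event per
#' row) into a numeric event matrix. Channel selection is by name; row
#' order is preserved.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"tsv"`. The binary
#'   FCS container is not supported by this package; export events to
#'   CSV/TSV first.
#' @param channels Optional character vector of channels to keep, in the
#'   requested order.
#' @return Numeric matrix with channel names as column names.
#' @export
read_sample <- function(path, format = c("auto", "csv", "tsv", "fcs"),
                        channels = NULL) {
  format <- match.arg(format)
  if (format == "fcs" || (format == "auto" && grepl("\\.fcs$", path,
                                                    ignore.case = TRUE)))
    stop("FCS files are not supported; export events to CSV/TSV first")
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv"
              else "csv"
  sep <- if (format == "tsv") "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e)))
  if (nrow(df) == 0) stop("empty sample file: ", path)
  if (!is.null(channels)) {
    missing <- setdiff(channels, names(df))
    if (length(missing))
      stop("channel(s) not present in ", path, ": ",
           paste(missing, collapse = ", "))
    df <- df[, channels, drop = FALSE]
  }
  bad <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric values in channel(s): ", paste(bad, collapse = ", "))
  as.matrix(df)
}

#' Write one sample's event matrix
#'
#' @param x Numeric event matrix with column names.
#' @param path Output path; extension picks the delimiter (`.tsv`/`.txt`
#'   tab, otherwise comma).
#' @return Invisibly, `path`.
#' @export
write_sample <- function(x, path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.matrix(x), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Preprocess a batch: log transform and standardise
#'
#' Applies the usual cytometry preprocessing: selected channels are mapped
#' `x -> log(x + shift)` with a per-channel shift (0 when the channel is
#' strictly positive, otherwise `1 - min(x)` so the smallest value maps to
#' `log(1) = 0`), then every channel is divided by its standard deviation
#' pooled across the whole batch (or per sample) so channels have unit
#' variance. The fitted transformation parameters are returned and can be
#' re-applied to new data with [apply_preprocess()].
#'
#' @param batch List of event matrices with column names.
#' @param log_channels Character vector of channels to log-transform
#'   (`NULL` = none, `"all"` = every channel).
#' @param standardize Divide each channel by its (pooled) standard
#'   deviation.
#' @param per_sample Standardise each sample separately instead of pooling.
#' @return A list with `batch` (transformed) and `params`
#'   (an `"aspire_preprocess"` object).
#' @export
preprocess_batch <- function(batch, log_channels = NULL, standardize = TRUE,
                             per_sample = FALSE) {
  batch <- as_batch(batch)
  chans <- colnames(batch[[1]])
  if (is.null(chans)) chans <- paste0("ch", seq_len(ncol(batch[[1]])))
  batch <- lapply(batch, function(m) { colnames(m) <- chans; m })
  if (identical(log_channels, "all")) log_channels <- chans
  if (length(setdiff(log_channels, chans)))
    stop("unknown channel(s): ",
         paste(setdiff(log_channels, chans), collapse = ", "))
  shifts <- stats::setNames(rep(0, length(chans)), chans)
  for (ch in log_channels) {
    mn <- min(vapply(batch, function(m) min(m[, ch]), numeric(1)))
    shifts[ch] <- if (mn > 0) 0 else 1 - mn
    batch <- lapply(batch, function(m) { m[, ch] <- log(m[, ch] + shifts[[ch]]); m })
  }
  sds <- NULL
  if (standardize) {
    if (per_sample) {
      batch <- lapply(batch, function(m) {
        s <- apply(m, 2, stats::sd)
        check_sd(s)
        sweep(m, 2, s, `/`)
      })
    } else {
      pooled <- do.call(rbind, batch)
      sds <- apply(pooled, 2, stats::sd)
      check_sd(sds)
      batch <- lapply(batch, function(m) sweep(m, 2, sds, `/`))
    }
  }
  params <- structure(list(channels = chans, log_channels = log_channels,
                           shifts = shifts, sds = sds,
                           standardize = standardize,
                           per_sample = per_sample),
                      class = "aspire_preprocess")
  list(batch = batch, params = params)
}

check_sd <- function(s) {
  if (any(s == 0))
    stop("zero-variance channel(s): ",
         paste(names(s)[s == 0], collapse = ", "))
}

#' Apply stored preprocessing parameters to new data
#'
#' Re-applies the exact transform fitted by [preprocess_batch()] (same
#' shifts, same pooled standard deviations) to a new batch, so training and
#' test data live on the same scale. Not available for `per_sample`
#' standardisation, which has no reusable parameters.
#'
#' @param params An `"aspire_preprocess"` object.
#' @param batch List of event matrices.
#' @return The transformed batch.
#' @export
apply_preprocess <- function(params, batch) {
  stopifnot(inherits(params, "aspire_preprocess"))
  batch <- as_batch(batch)
  if (params$per_sample)
    stop("per-sample standardisation has no reusable parameters")
  lapply(batch, function(m) {
    colnames(m) <- params$channels
    for (ch in params$log_channels) m[, ch] <- log(m[, ch] + params$shifts[[ch]])
    if (params$standardize) m <- sweep(m, 2, params$sds, `/`)
    m
  })
}

#' Subsample events per sample
#'
#' Uniform without-replacement subsampling of each sample, either to a
#' fraction of its events or to a fixed count; seeded and reproducible.
#'
#' @param batch List of event matrices.
#' @param fraction Fraction in `(0, 1]` of each sample's events to keep.
#' @param count Fixed number of events to keep per sample (must not exceed
#'   any sample's size). Exactly one of `fraction`/`count` must be given.
#' @param seed Integer seed.
#' @return The subsampled batch.
#' @export
subsample_batch <- function(batch, fraction = NULL, count = NULL, seed = 1L) {
  batch <- as_batch(batch)
  if (is.null(fraction) == is.null(count))
    stop("give exactly one of 'fraction' or 'count'")
  if (!is.null(fraction) && (fraction <= 0 || fraction > 1))
    stop("'fraction' must be in (0, 1]")
  set.seed(seed)
  lapply(batch, function(m) {
    k <- if (!is.null(count)) count else round(fraction * nrow(m))
    if (k > nrow(m))
      stop("requested ", k, " events from a sample of ", nrow(m))
    m[sort(sample.int(nrow(m), k)), , drop = FALSE]
  })
}
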