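## Plain-text serialization: behavioral sessions as one-row-per-trial CSV,
## neural sessions as long-format rates CSV + labels CSV + JSON metadata
## sidecar. Validation errors name the offending field and row.

#' Write / read a behavioral session as CSV
#'
#' Columns are the trial-table columns of [generateTaskSession()]
#' (probabilities as fractions, stakes in mL, sides as L/R, times in ms,
#' durations in s).
#'
#' @param session a [BehavioralSession-class].
#' @param path CSV file path.
#' @return `writeBehavioralSession` the path, invisibly;
#'   `readBehavioralSession` a validated [BehavioralSession-class].
#' @export
writeBehavioralSession <- function(session, path) {
  tr <- trials(session)
  attr(tr, "removed") <- NULL
  write.csv(cbind(tr, subjectId = session@subjectId,
                  sessionSeed = session@seed),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBehavioralSession
#' @export
readBehavioralSession <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("prob1", "prob2")) {
    bad <- which(tr[[col]] < 0 | tr[[col]] > 1)
    if (length(bad))
      stop("invalid ", col, " outside [0, 1] at row ", bad[1],
           " (value ", tr[[col]][bad[1]], ")")
  }
  bad <- which(tr$side1 == tr$side2)
  if (length(bad))
    stop("offers on the same side at row ", bad[1])
  subj <- if ("subjectId" %in% names(tr)) tr$subjectId[1] else "unknown"
  seed <- if ("sessionSeed" %in% names(tr)) tr$sessionSeed[1] else
    NA_integer_
  tr$subjectId <- NULL; tr$sessionSeed <- NULL
  new("BehavioralSession", trials = tr, subjectId = as.character(subj),
      seed = as.integer(seed))
}

#' Write / read a neural session as plain-text files
#'
#' Writes `<base>_rates.csv` (long format: trial, neuron, bin, rate),
#' `<base>_labels.csv` (per-trial condition labels) and `<base>_meta.json`
#' (bin geometry, offer onsets, alignment, seed).
#'
#' @param neural a [NeuralSession-class].
#' @param base file-path base (no extension).
#' @return `writeNeuralSession` the base path, invisibly;
#'   `readNeuralSession` a validated [NeuralSession-class].
#' @export
writeNeuralSession <- function(neural, base) {
  d <- dim(neural@rates)
  long <- data.frame(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    neuron = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    bin = rep(seq_len(d[3]), each = d[1] * d[2]),
    rate = as.vector(neural@rates))
  write.csv(long, paste0(base, "_rates.csv"), row.names = FALSE)
  write.csv(conditionLabels(neural), paste0(base, "_labels.csv"),
            row.names = FALSE)
  meta <- list(dims = d, binWidth = neural@binWidth,
               binStarts = neural@binStarts,
               offerOnsets = neural@offerOnsets,
               alignment = neural@alignment, seed = neural@seed)
  jsonlite::write_json(meta, paste0(base, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(base)
}

#' @rdname writeNeuralSession
#' @export
readNeuralSession <- function(base) {
  meta <- jsonlite::read_json(paste0(base, "_meta.json"),
                              simplifyVector = TRUE)
  long <- read.csv(paste0(base, "_rates.csv"))
  lab <- read.csv(paste0(base, "_labels.csv"), stringsAsFactors = FALSE)
  d <- as.integer(meta$dims)
  if (nrow(long) != prod(d))
    stop("rates file has ", nrow(long), " rows; metadata implies ",
         prod(d))
  if (nrow(lab) != d[1])
    stop("labels have ", nrow(lab), " rows for ", d[1],
         " trials in the rates tensor")
  arr <- array(NA_real_, d)
  arr[cbind(long$trial, long$neuron, long$bin)] <- long$rate
  if ("cond" %in% names(lab)) lab$cond <- as.character(lab$cond)
  new("NeuralSession", rates = arr, binWidth = meta$binWidth,
      binStarts = as.numeric(meta$binStarts),
      offerOnsets = as.numeric(meta$offerOnsets), labels = lab,
      alignment = meta$alignment, seed = as.integer(meta$seed))
}
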