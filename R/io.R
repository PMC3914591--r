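# Readers and writers for plain-text signal, feature and report files.

#' Read a one-sample-per-line ASCII segment file
#'
#' Reads segment files in the common single-channel ASCII layout: one
#' numeric sample per line, one file per segment. Blank lines are
#' ignored; any non-numeric line raises an error naming its line number.
#' The default sampling rate of 173.61 Hz matches the classic short-term
#' segment archives; override it for other sources.
#'
#' @param path file path.
#' @param label class label to attach (the file format itself carries no
#'   label; by convention it comes from the directory or file-name
#'   prefix). Default `NA` (unlabeled).
#' @param sampleRate sampling rate in Hz (default 173.61).
#' @return a [Signal-class] with `sourceId` set to the file name.
#' @seealso [writeBonnAscii()], [readMultichannelCsv()]
#' @export
readBonnAscii <- function(path, label = NA, sampleRate = 173.61) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    keep <- trimws(lines) != ""
    if (!any(keep))
        stop("empty signal file: ", path, call. = FALSE)
    vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
    if (anyNA(vals)) {
        badLine <- which(keep)[which(is.na(vals))[1L]]
        stop(sprintf("non-numeric sample at %s line %d: '%s'",
                     path, badLine, lines[badLine]), call. = FALSE)
    }
    Signal(vals, sampleRate, classLabel = label, sourceId = basename(path))
}

#' Write a signal as a one-sample-per-line ASCII file
#'
#' Round-trips with [readBonnAscii()]: samples are written at full
#' precision (17 significant digits), one per line.
#'
#' @param signal a [Signal-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeBonnAscii <- function(signal, path) {
    stopifnot(is(signal, "Signal"))
    writeLines(formatC(signal@samples, format = "g", digits = 17), path)
    invisible(path)
}

#' Read a delimited multichannel record as one Signal per column
#'
#' Reads a rectangular numeric table (CSV by default) with one column
#' per channel and an optional header row of channel names. Ragged rows
#' raise an error naming the first offending row. Each column becomes
#' one single-channel [Signal-class] with `sourceId` `"file:column"`;
#' the analysis pipeline is strictly channel-wise.
#'
#' @param path file path.
#' @param sampleRate sampling rate in Hz (default 256).
#' @param label class label attached to every channel (default `NA`).
#' @param sep field separator (default `","`).
#' @return list of [Signal-class] objects, one per column.
#' @seealso [writeMultichannelCsv()]
#' @export
readMultichannelCsv <- function(path, sampleRate = 256, label = NA,
                                sep = ",") {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    counts <- utils::count.fields(path, sep = sep)
    counts <- counts[!is.na(counts)]
    if (length(counts) == 0L) stop("empty file: ", path, call. = FALSE)
    if (length(unique(counts)) > 1L)
        stop(sprintf("ragged table in %s: row %d has %d fields, expected %d",
                     path, which(counts != counts[1L])[1L],
                     counts[counts != counts[1L]][1L], counts[1L]),
             call. = FALSE)
    firstRow <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
    hasHeader <- anyNA(suppressWarnings(as.numeric(firstRow)))
    df <- utils::read.table(path, header = hasHeader, sep = sep,
                            colClasses = "numeric",
                            check.names = FALSE)
    if (!hasHeader) names(df) <- sprintf("ch%d", seq_along(df))
    lapply(seq_along(df), function(j)
        Signal(df[[j]], sampleRate, classLabel = label,
               sourceId = sprintf("%s:%s", basename(path), names(df)[j])))
}

#' Write channel signals as a delimited multichannel file
#'
#' @param signals list of equal-length [Signal-class] objects (the
#'   channels).
#' @param path output path.
#' @param sep field separator (default `","`).
#' @return `path`, invisibly.
#' @export
writeMultichannelCsv <- function(signals, path, sep = ",") {
    stopifnot(is.list(signals), length(signals) >= 1L,
              all(vapply(signals, is, logical(1), class2 = "Signal")))
    lens <- vapply(signals, length, integer(1))
    if (length(unique(lens)) != 1L)
        stop("all channels must have equal length", call. = FALSE)
    df <- as.data.frame(lapply(signals, function(s)
        formatC(s@samples, format = "g", digits = 17)))
    names(df) <- vapply(signals, function(s) s@sourceId, character(1))
    utils::write.table(df, path, sep = sep, row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
    invisible(path)
}

#' Write a window matrix to CSV for inspection
#'
#' One row per window: the `l` samples, then `label`, `source_id` and
#' `window_index` columns.
#'
#' @param wm a [WindowMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeWindowMatrixCsv <- function(wm, path) {
    stopifnot(is(wm, "WindowMatrix"))
    df <- as.data.frame(wm@windowData)
    names(df) <- sprintf("s%d", seq_len(ncol(df)))
    df$label <- wm@rowLabels
    df$source_id <- wm@rowSources
    df$window_index <- wm@rowWindows
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Write a feature set to CSV
#'
#' The interchange surface of the pipeline: columns `source_id`,
#' `window_index`, `f1 .. fd`, `label`. Feature files are suitable for
#' 3-D scatter plotting of the default schemes and are what the CV
#' commands consume and produce. Identical inputs produce byte-identical
#' files.
#'
#' @param fs a [FeatureSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readFeatureCsv()]
#' @export
writeFeatureCsv <- function(fs, path) {
    stopifnot(is(fs, "FeatureSet"))
    vals <- fs@featureValues
    df <- data.frame(source_id = fs@rowSources,
                     window_index = fs@rowWindows,
                     stringsAsFactors = FALSE)
    for (j in seq_len(ncol(vals)))
        df[[sprintf("f%d", j)]] <- formatC(vals[, j], format = "g",
                                           digits = 17)
    df$label <- fs@rowLabels
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a feature CSV written by [writeFeatureCsv()]
#'
#' @param path feature CSV path.
#' @param scheme scheme tag to attach (`"FFPC"`, `"PCPEM"` or `"EM"`);
#'   the CSV layout itself is scheme-agnostic.
#' @return a [FeatureSet-class].
#' @export
readFeatureCsv <- function(path, scheme = c("FFPC", "PCPEM", "EM")) {
    scheme <- match.arg(scheme)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
    if (length(fcols) == 0L)
        stop("no feature columns (f1..fd) found in ", path, call. = FALSE)
    new("FeatureSet",
        featureValues = as.matrix(df[fcols]),
        featureScheme = scheme,
        rowLabels = as.character(df$label),
        rowSources = as.character(df$source_id),
        rowWindows = as.integer(df$window_index))
}

cvReportAsList <- function(report) {
    list(fold_accuracies = report@foldAccuracies,
         mean_accuracy = report@meanAccuracy,
         sd_accuracy = report@sdAccuracy,
         fold_segment_accuracies = report@foldSegmentAccuracies,
         confusion_totals = report@confusionTotals,
         config = report@configEcho)
}

#' Serialize a CVReport to JSON
#'
#' Writes fold accuracies, mean, sd, the secondary segment-level
#' accuracies, confusion totals and the full configuration echo
#' (including seeds), so the report is self-describing and reproducible.
#'
#' @param report a [CVReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCVReportJSON <- function(report, path) {
    stopifnot(is(report, "CVReport"))
    jsonlite::write_json(cvReportAsList(report), path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", pretty = TRUE)
    invisible(path)
}

#' Serialize a CVReport as a one-row CSV
#'
#' One row per report with the configuration and the aggregated
#' accuracies, suitable for assembling method-by-window-length results
#' tables across runs.
#'
#' @param report a [CVReport-class].
#' @param path output path.
#' @param append append without header to an existing table.
#' @return `path`, invisibly.
#' @export
writeCVReportCSV <- function(report, path, append = FALSE) {
    stopifnot(is(report, "CVReport"))
    cfg <- report@configEcho
    df <- data.frame(
        scheme = cfg$scheme,
        window_length = cfg$window_length,
        d = cfg$d,
        k = cfg$k,
        seed = cfg$seed,
        standardize = cfg$standardize,
        mean_accuracy = report@meanAccuracy,
        sd_accuracy = report@sdAccuracy,
        mean_segment_accuracy = mean(report@foldSegmentAccuracies),
        stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = ",", row.names = FALSE,
                       col.names = !append, append = append, quote = FALSE)
    invisible(path)
}

runConfigDefaults <- function() {
    list(window_length = 512L, scheme = "PCPEM", n_components = 3L,
         n_pcs = 2L, energy_truncation = NULL, k = 10L, seed = 1L,
         standardize = NULL, preset = NULL, input = NULL,
         label_map = NULL, group_map = NULL, sample_rate = NULL,
         output_dir = ".",
         window_grid = NULL, n_signals_per_class = NULL,
         signal_length = NULL)
}

#' Read and validate a run configuration (YAML or JSON)
#'
#' A configuration fully determines one run: window length (or grid),
#' scheme, feature dimensions, energy truncation, fold count, master
#' seed, standardization flag, input locations with a label map, and the
#' output directory. Unknown keys fail fast with an error listing them.
#'
#' @param path `.yaml`/`.yml` or `.json` configuration file.
#' @return named list of configuration values merged over the defaults.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
    cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
        yaml::read_yaml(path)
    else if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::read_json(path, simplifyVector = TRUE)
    else stop("config must be .yaml, .yml or .json: ", path, call. = FALSE)
    defaults <- runConfigDefaults()
    unknown <- setdiff(names(cfg), names(defaults))
    if (length(unknown))
        stop("unknown config keys: ", paste(unknown, collapse = ", "),
             call. = FALSE)
    utils::modifyList(defaults, cfg)
}
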