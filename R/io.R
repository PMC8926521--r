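# Readers and writers for the pipeline's text formats: signal records,
# beat annotations, cohort tables, model files and analysis reports.
# All formats are UTF-8, tab-delimited, "." decimal separator, 0-based
# sample indexing.

BEAT_CLASSES <- c("NORMAL", "PVC", "OTHER")

#' Write an ECG record as delimited text
#'
#' Header lines (prefixed `#`) carry the sampling rate and lead names; the
#' body is one tab-delimited row per sample, one column per lead, in mV at
#' full double precision (round-trip exact).
#'
#' @param record An [ecg_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# fs\t%.10g", record$fs),
               paste(c("# leads", record$leads), collapse = "\t")), con)
  body <- apply(record$signal, 1, function(row)
    paste(sprintf("%.17g", row), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Load an ECG record
#'
#' @param path File path.
#' @param format `"auto"` (by extension: `.hea` dispatches to the MIT-BIH
#'   reader), `"text"` (the [write_record()] format) or `"mitbih"`
#'   (header + 212-format signal file).
#' @return An [ecg_record()].
#' @export
load_record <- function(path, format = c("auto", "text", "mitbih")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.hea$", path)) "mitbih" else "text"
  if (format == "mitbih") return(load_record_mitbih(path))
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines)
  header <- lines[hdr]
  fs_line <- grep("^# fs\t", header, value = TRUE)
  if (!length(fs_line))
    stop_invalid("record header is missing the 'fs' field")
  fs <- as.numeric(sub("^# fs\t", "", fs_line[1]))
  leads_line <- grep("^# leads\t", header, value = TRUE)
  if (!length(leads_line))
    stop_invalid("record header is missing the 'leads' field")
  leads <- strsplit(sub("^# leads\t", "", leads_line[1]), "\t")[[1]]

  body_idx <- setdiff(seq_along(lines), hdr)
  body <- lines[body_idx]
  body <- body[nzchar(body)]
  if (!length(body)) stop_invalid("record has no samples")
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != length(leads))
  if (length(bad))
    stop_invalid("parse error at line %d: %d fields, expected %d leads",
                 body_idx[bad[1]], nf[bad[1]], length(leads))
  sig <- matrix(as.numeric(unlist(parts)), ncol = length(leads),
                byrow = TRUE)
  if (anyNA(sig))
    stop_invalid("parse error: non-numeric sample value in %s", path)
  ecg_record(sig, fs, leads)
}

# Minimal MIT-BIH-compatible reader: record header (.hea) plus a 212-format
# signal file. Two 12-bit two's-complement samples are packed per 3 bytes;
# amplitudes are converted to mV via the per-signal gain (adu/mV).
load_record_mitbih <- function(hea_path) {
  if (!file.exists(hea_path)) stop_invalid("file not found: %s", hea_path)
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(top[3]) else 250
  sig_lines <- lines[2:(1 + nsig)]
  fields <- strsplit(trimws(sig_lines), "\\s+")
  dat_file <- fields[[1]][1]
  fmt <- sub("x.*$", "", fields[[1]][2])
  if (fmt != "212")
    stop_invalid("unsupported MIT-BIH signal format '%s' (only 212)", fmt)
  gains <- vapply(fields, function(f)
    if (length(f) >= 3) as.numeric(sub("[(/].*$", "", f[3])) else 200,
    numeric(1))
  gains[!is.finite(gains) | gains == 0] <- 200
  leads <- vapply(seq_len(nsig), function(i) {
    f <- fields[[i]]
    if (length(f) >= 9) paste(f[9:length(f)], collapse = " ")
    else paste0("S", i)
  }, character(1))

  dat_path <- file.path(dirname(hea_path), dat_file)
  if (!file.exists(dat_path)) stop_invalid("signal file not found: %s", dat_path)
  raw <- readBin(dat_path, "integer", n = file.info(dat_path)$size,
                 size = 1, signed = FALSE)
  ntrip <- length(raw) %/% 3
  b1 <- raw[seq(1, by = 3, length.out = ntrip)]
  b2 <- raw[seq(2, by = 3, length.out = ntrip)]
  b3 <- raw[seq(3, by = 3, length.out = ntrip)]
  s1 <- bitwAnd(b2, 15L) * 256L + b1
  s2 <- bitwAnd(b2 %/% 16L, 15L) * 256L + b3
  tc <- function(v) ifelse(v > 2047L, v - 4096L, v)
  samples <- as.numeric(rbind(tc(s1), tc(s2)))
  ns <- (length(samples) %/% nsig) * nsig
  sig <- matrix(samples[seq_len(ns)], ncol = nsig, byrow = TRUE)
  sig <- sweep(sig, 2, gains, "/")
  ecg_record(sig, fs, leads)
}

#' Write beat annotations
#'
#' One row per beat: `sample_index<TAB>class`, 0-based.
#'
#' @param annotations Data.frame with `sample` and `class` columns.
#' @param path Output path.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(all(c("sample", "class") %in% names(annotations)))
  writeLines(sprintf("%d\t%s", annotations$sample, annotations$class),
             con = path)
  invisible(path)
}

#' Load beat annotations
#'
#' Validates 0-based, sorted, non-negative sample indices and known beat
#' class tokens; an empty file is a valid empty annotation set.
#'
#' @param path File path.
#' @return Data.frame with `sample` (integer) and `class` columns.
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(sample = integer(), class = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop_invalid("annotation rows must be 'sample_index<TAB>class'")
  idx <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
  cls <- vapply(parts, `[`, "", 2)
  if (anyNA(idx) || any(idx < 0))
    stop_invalid("annotation sample indices must be non-negative integers")
  if (is.unsorted(idx))
    stop_invalid("annotation sample indices must be sorted")
  bad <- setdiff(unique(cls), BEAT_CLASSES)
  if (length(bad))
    stop_invalid("unknown beat class token '%s' (known: %s)", bad[1],
                 paste(BEAT_CLASSES, collapse = ", "))
  data.frame(sample = idx, class = cls, stringsAsFactors = FALSE)
}

#' Write / load a cohort table
#'
#' Tab-delimited with a header row naming every column.
#'
#' @param table A cohort data.frame.
#' @param path File path.
#' @export
write_cohort <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

# Recursively strip S3 classes so report bundles serialise predictably.
as_plain <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(unclass(x), as_plain))
  x
}

#' Write an analysis report
#'
#' JSON output preserves full precision and deterministic field order (the
#' same bundle always produces byte-identical files); markdown renders the
#' clinical tables of a `cohort_report` or the run table of a
#' `benchmark_report` for human reading.
#'
#' @param bundle A report object (`cohort_report`, `benchmark_report`, or
#'   any nested list of results).
#' @param path Output path.
#' @param format `"json"` or `"markdown"`.
#' @export
write_report <- function(bundle, path, format = c("json", "markdown")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(as_plain(bundle), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    return(invisible(path))
  }
  writeLines(report_to_markdown(bundle), path)
  invisible(path)
}

md_table <- function(df) {
  fmt <- function(v) if (is.numeric(v)) sprintf("%.4g", v) else as.character(v)
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1)
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}

report_to_markdown <- function(bundle) {
  if (inherits(bundle, "benchmark_report")) {
    return(c("# Classifier benchmark", "", md_table(bundle$runs), "",
             sprintf("Median test accuracy: Gentle AdaBoost %.3f, back-propagation %.3f (margin %.3f).",
                     bundle$summary$median_gentleboost,
                     bundle$summary$median_backprop, bundle$summary$margin)))
  }
  if (inherits(bundle, "cohort_report")) {
    out <- c("# Cohort analysis", "", "## Group comparison")
    gt <- bundle$group_tests
    gt_df <- data.frame(variable = names(gt),
                        test = vapply(gt, `[[`, "", "type"),
                        statistic = as.numeric(vapply(gt, `[[`, "", "stat")),
                        p = as.numeric(vapply(gt, `[[`, "", "p")),
                        row.names = NULL, stringsAsFactors = FALSE)
    out <- c(out, md_table(gt_df), "", "## Logistic regression",
             md_table(bundle$logistic$coefficients), "",
             "## Marker performance")
    mk <- bundle$markers
    mk_df <- data.frame(
      marker = names(mk),
      auc = vapply(mk, `[[`, numeric(1), "auc"),
      cutoff = vapply(mk, `[[`, numeric(1), "cutoff"),
      sensitivity = vapply(mk, function(m) m$metrics$sensitivity, numeric(1)),
      specificity = vapply(mk, function(m) m$metrics$specificity, numeric(1)),
      ppv = vapply(mk, function(m) m$metrics$ppv, numeric(1)),
      npv = vapply(mk, function(m) m$metrics$npv, numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
    return(c(out, md_table(mk_df)))
  }
  c("# Report", "", "```json",
    jsonlite::toJSON(as_plain(bundle), auto_unbox = TRUE, digits = NA,
                     pretty = TRUE, na = "null"),
    "```")
}

#' Serialise / restore a trained classifier
#'
#' Gentle AdaBoost models are stored as a JSON list of stumps
#' (feature / threshold / side responses); back-propagation networks as
#' nested weight arrays with their input standardisation.
#'
#' @param model A `gentle_adaboost` or `backprop_mlp` object.
#' @param path File path.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "gentle_adaboost")) {
    payload <- list(type = "gentle_adaboost", n_iter = model$n_iter,
                    stumps = lapply(model$stumps, function(s)
                      list(feature = s$feature, threshold = s$threshold,
                           left = s$left, right = s$right)))
  } else if (inherits(model, "backprop_mlp")) {
    payload <- list(type = "backprop_mlp", hidden = model$hidden,
                    W1 = model$W1, W2 = model$W2)
  } else stop_invalid("unsupported model class")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(p$type, "gentle_adaboost")) {
    stumps <- lapply(seq_len(nrow(p$stumps)), function(i)
      structure(list(feature = p$stumps$feature[i],
                     threshold = p$stumps$threshold[i],
                     left = p$stumps$left[i], right = p$stumps$right[i]),
                class = "stump"))
    return(structure(list(stumps = stumps, n_iter = p$n_iter),
                     class = "gentle_adaboost"))
  }
  if (identical(p$type, "backprop_mlp")) {
    return(structure(list(W1 = as.matrix(p$W1), W2 = as.matrix(p$W2),
                          hidden = p$hidden),
                     class = "backprop_mlp"))
  }
  stop_invalid("unknown model type in %s", path)
}
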