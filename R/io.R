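# Plain-text file formats: frame streams, dataset TXT, model/bundle JSON,
# event JSON-lines and session reports. All artifacts carry a format version
# and, where applicable, the seed and a config hash, so identical inputs
# reproduce byte-identical payloads.

FORMAT_VERSION <- "1.0"

# 31-bit polynomial rolling hash over a string; stable provenance hash for
# config lists (exact in double arithmetic)
config_hash <- function(x) {
  s <- paste(deparse(x, control = c("keepNA", "niceNames")), collapse = "")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

fmt6 <- function(v) formatC(v, format = "f", digits = 6)

#' Read and write frame streams
#'
#' One frame per line: `timestamp joint:x,y,z joint:x,y,z ...`, coordinates at
#' six decimal places, undetected joints omitted, `#` comment lines ignored.
#' Writing then reading reproduces the file bit-exactly.
#'
#' @param stream List of [skel_frame()]s.
#' @param path File path.
#' @return `write_stream` returns `path` invisibly; `read_stream` the list of
#'   frames.
#' @export
write_stream <- function(stream, path) {
  lines <- vapply(stream, function(f) {
    det <- names(which(f$detected))
    toks <- vapply(det, function(j)
      sprintf("%s:%s,%s,%s", j, fmt6(f$positions[j, 1L]),
              fmt6(f$positions[j, 2L]), fmt6(f$positions[j, 3L])),
      character(1L))
    paste(c(fmt6(f$timestamp), toks), collapse = " ")
  }, character(1L))
  writeLines(c(sprintf("# skelwatch frame stream v%s", FORMAT_VERSION), lines), path)
  invisible(path)
}

#' @rdname write_stream
#' @export
read_stream <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  last_t <- -Inf
  lapply(lines, function(l) {
    toks <- strsplit(trimws(l), "\\s+")[[1L]]
    t <- suppressWarnings(as.numeric(toks[1L]))
    if (is.na(t)) stop_skel(paste("bad stream line:", l), "bad_format")
    if (t <= last_t) stop_skel("stream timestamps must be strictly increasing", "bad_format")
    last_t <<- t
    pos <- list()
    for (tk in toks[-1L]) {
      parts <- strsplit(tk, ":", fixed = TRUE)[[1L]]
      if (length(parts) != 2L) stop_skel(paste("bad joint token:", tk), "bad_format")
      xyz <- suppressWarnings(
        as.numeric(strsplit(parts[2L], ",", fixed = TRUE)[[1L]]))
      if (length(xyz) != 3L || anyNA(xyz))
        stop_skel(paste("bad joint token:", tk), "bad_format")
      pos[[parts[1L]]] <- xyz
    }
    skel_frame(t, pos)
  })
}

#' Read and write dataset TXT files
#'
#' One sample per line: feature values space-separated at six decimal places,
#' final token the class label. `#` header lines record the joint set, window
#' and seed.
#'
#' @param dataset A `posture_dataset`.
#' @param path File path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` a
#'   `posture_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "posture_dataset"))
  hdr <- c(sprintf("# skelwatch dataset v%s", FORMAT_VERSION),
           sprintf("# joint_set %s", paste(dataset$joint_set, collapse = ",")),
           sprintf("# window %d", dataset$window),
           sprintf("# seed %d", dataset$seed),
           sprintf("# classes %s", paste(levels(dataset$labels), collapse = ",")))
  body <- vapply(seq_len(nrow(dataset$x)), function(i)
    paste(c(fmt6(dataset$x[i, ]), as.character(dataset$labels[i])), collapse = " "),
    character(1L))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  get_hdr <- function(key) {
    m <- hdr[grepl(paste0("^# ", key, " "), hdr)]
    if (length(m)) sub(paste0("^# ", key, " "), "", m[1L]) else NULL
  }
  joint_set <- strsplit(get_hdr("joint_set") %||% "", ",")[[1L]]
  window <- as.integer(get_hdr("window") %||% "1")
  seed <- as.integer(get_hdr("seed") %||% NA)
  classes <- strsplit(get_hdr("classes") %||% "", ",")[[1L]]
  toks <- strsplit(trimws(body), "\\s+")
  labs <- vapply(toks, function(tk) tk[length(tk)], character(1L))
  x <- t(vapply(toks, function(tk) suppressWarnings(as.numeric(tk[-length(tk)])),
                numeric(length(toks[[1L]]) - 1L)))
  if (anyNA(x)) stop_skel("non-numeric feature value in dataset", "bad_format")
  posture_dataset(x, factor(labs, levels = if (length(classes)) classes else sort(unique(labs))),
                  if (length(joint_set)) joint_set else "head", window, seed)
}

mlp_to_list <- function(net) {
  list(format_version = FORMAT_VERSION,
       kind = "skelwatch_mlp",
       config = net$config,
       config_hash = config_hash(net$config),
       levels = as.list(net$levels),
       transfer = net$transfer,
       epochs = net$epochs, converged = net$converged,
       final_error = net$final_error,
       weights = list(W1 = net$W1, b1 = net$b1, W2 = net$W2, b2 = net$b2))
}

mlp_from_list <- function(l) {
  w <- l$weights
  net <- structure(list(
    W1 = matrix(unlist(w$W1), nrow = length(w$b1), byrow = FALSE),
    b1 = as.numeric(unlist(w$b1)),
    W2 = matrix(unlist(w$W2), nrow = length(w$b2), byrow = FALSE),
    b2 = as.numeric(unlist(w$b2)),
    transfer = l$transfer,
    config = l$config, levels = unlist(l$levels),
    epochs = l$epochs, converged = l$converged, final_error = l$final_error
  ), class = "mlp")
  # jsonlite serializes matrices row-major as lists of rows; rebuild properly
  net$W1 <- do.call(rbind, lapply(w$W1, as.numeric))
  net$W2 <- do.call(rbind, lapply(w$W2, as.numeric))
  net
}

#' Save and load trained networks as JSON
#'
#' A single JSON document holding the configuration, label map, weights
#' (row-major) and provenance; loading reproduces the network's outputs
#' bit-exactly.
#'
#' @param net A fitted [mlp()].
#' @param path File path.
#' @return `write_mlp` returns `path` invisibly; `read_mlp` the network.
#' @export
write_mlp <- function(net, path) {
  stopifnot(inherits(net, "mlp"))
  l <- mlp_to_list(net)
  l$weights <- list(W1 = apply(net$W1, 1L, as.list, simplify = FALSE),
                    b1 = as.list(net$b1),
                    W2 = apply(net$W2, 1L, as.list, simplify = FALSE),
                    b2 = as.list(net$b2))
  jsonlite::write_json(l, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  l <- jsonlite::read_json(path)
  if (!identical(l$kind, "skelwatch_mlp")) stop_skel("not a skelwatch model file", "bad_format")
  mlp_from_list(l)
}

#' Save and load classifier bundles
#'
#' The network JSON plus joint set, window and decoding thresholds.
#'
#' @param bundle A `classifier_bundle`.
#' @param path File path.
#' @return `write_bundle` returns `path` invisibly; `read_bundle` the bundle.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "classifier_bundle"))
  l <- mlp_to_list(bundle$mlp)
  l$weights <- list(W1 = apply(bundle$mlp$W1, 1L, as.list, simplify = FALSE),
                    b1 = as.list(bundle$mlp$b1),
                    W2 = apply(bundle$mlp$W2, 1L, as.list, simplify = FALSE),
                    b2 = as.list(bundle$mlp$b2))
  doc <- list(format_version = FORMAT_VERSION, kind = "skelwatch_bundle",
              joint_set = as.list(bundle$joint_set), window = bundle$window,
              confidence_threshold = bundle$confidence_threshold,
              margin = bundle$margin, model = l)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$kind, "skelwatch_bundle")) stop_skel("not a bundle file", "bad_format")
  js <- unlist(doc$joint_set)
  structure(list(mlp = mlp_from_list(doc$model),
                 joint_set = js, window = as.integer(doc$window),
                 confidence_threshold = doc$confidence_threshold,
                 margin = doc$margin),
            class = "classifier_bundle")
}

#' Write and read alarm event logs
#'
#' JSON-lines, one event per line, schema-versioned.
#'
#' @param events Event data frame from [run_monitor()].
#' @param path File path.
#' @return `write_events` returns `path` invisibly; `read_events` the data frame.
#' @export
write_events <- function(events, path) {
  lines <- vapply(seq_len(nrow(events)), function(i)
    as.character(jsonlite::toJSON(c(list(schema_version = FORMAT_VERSION),
                                    as.list(events[i, ])),
                                  auto_unbox = TRUE, digits = NA)),
    character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(no_events())
  rows <- lapply(lines, function(l) {
    e <- jsonlite::fromJSON(l)
    data.frame(kind = e$kind, timestamp = e$timestamp,
               from_stage = e$from_stage, to_stage = e$to_stage,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a rehabilitation session report as JSON
#'
#' @param report A `session_report`.
#' @param path File path.
#' @return `path` invisibly.
#' @export
write_session_report <- function(report, path) {
  stopifnot(inherits(report, "session_report"))
  doc <- list(schema_version = FORMAT_VERSION,
              max_train = report$max_train,
              postures = report$postures,
              prompts = report$prompts)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line, `#` comments ignored; values are parsed as
#' numbers where possible.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(trimws(lines), "#") & grepl("=", lines, fixed = TRUE)]
  out <- list()
  for (l in lines) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
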