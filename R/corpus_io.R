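#' Read a corpus of transcripts
#'
#' Reads one interview transcript per UTF-8 `.txt` file in a directory (the
#' `doc_id` is the filename stem), or one per record of a JSONL file with
#' fields `doc_id` and `text`.  Raw text round-trips byte-exactly, including
#' transcription marks such as the ellipsis.  Transcripts are returned in
#' lexicographic `doc_id` order (Unicode code points, C collation) for
#' reproducibility.
#'
#' @param path Directory of `.txt` files or a `.jsonl` file.
#' @param format `"auto"` (directory -> txt, file -> jsonl), `"txt"` or
#'   `"jsonl"`.
#' @return Named list of transcripts (`doc_id`, `raw_text`), class
#'   `lf_corpus`.
#' @export
read_corpus <- function(path, format = c("auto", "txt", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (format == "auto") format <- if (dir.exists(path)) "txt" else "jsonl"
  if (format == "txt") {
    files <- list.files(path, pattern = "\\.txt$", full.names = TRUE)
    ids <- sub("\\.txt$", "", basename(files))
    texts <- lapply(files, read_utf8_file)
  } else {
    lines <- read_utf8_lines(path)
    lines <- lines[nzchar(lines)]
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) stop("invalid JSON on line ", i,
                                               " of ", path, call. = FALSE))
      if (is.null(rec$doc_id)) stop("missing \"doc_id\" on line ", i,
                                    " of ", path, call. = FALSE)
      if (is.null(rec$text)) stop("missing \"text\" on line ", i,
                                  " of ", path, call. = FALSE)
      rec
    })
    ids <- vapply(recs, function(r) as.character(r$doc_id), "")
    texts <- lapply(recs, function(r) as.character(r$text))
  }
  if (anyDuplicated(ids))
    stop("duplicate doc_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ord <- order_c(ids)
  corpus <- Map(function(id, txt) list(doc_id = id, raw_text = txt),
                ids[ord], texts[ord])
  names(corpus) <- ids[ord]
  class(corpus) <- "lf_corpus"
  corpus
}

# lexicographic by Unicode code point, independent of the session locale
order_c <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  order(x)
}

read_utf8_file <- function(f) {
  raw <- readBin(f, "raw", file.info(f)$size)
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  if (!validUTF8(txt)) stop("file is not valid UTF-8: ", f)
  txt
}

read_utf8_lines <- function(f) {
  con <- file(f, encoding = "UTF-8")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Write a corpus to disk
#'
#' One UTF-8 `.txt` file per transcript, named `<doc_id>.txt`; byte-exact
#' inverse of [read_corpus()].
#'
#' @param corpus `lf_corpus` (or plain list of transcripts).
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (tr in corpus) {
    con <- file(file.path(path, paste0(tr$doc_id, ".txt")), "wb")
    writeBin(charToRaw(enc2utf8(tr$raw_text)), con)
    close(con)
  }
  invisible(path)
}

#' Read the cohort metadata table
#'
#' Expects a CSV with columns `doc_id`, `exposure` (A1 = directly exposed,
#' A2 = witness/threatened), `diagnosis` (full_ptsd / partial_ptsd /
#' no_ptsd), DSM-5 criterion flags `crit_B` \ldots `crit_G`, and
#' socio-demographics (`sex`, `age`, `education`, `profession`, `single`,
#' `living_alone`).  Enforces the partial-PTSD definition: re-experiencing
#' symptoms (criterion B) with significant distress/functional impairment
#' (criterion G), so `diagnosis == "partial_ptsd"` requires both flags.
#' Unknown columns are preserved.
#'
#' @param path CSV file.
#' @return data.frame with typed columns, one row per document.
#' @export
read_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("doc_id", "exposure", "diagnosis",
                "crit_B", "crit_C", "crit_D", "crit_E", "crit_G")
  missing <- setdiff(required, names(md))
  if (length(missing))
    stop("metadata is missing required columns: ", paste(missing, collapse = ", "))
  validate_metadata(md)
}

#' Validate a metadata table against the cohort invariants
#' @param md data.frame as in [read_metadata()].
#' @return The validated (typed) data.frame.
#' @export
validate_metadata <- function(md) {
  bad <- which(!md$exposure %in% c("A1", "A2"))
  if (length(bad))
    stop("invalid exposure value \"", md$exposure[bad[1]], "\" in row ", bad[1])
  bad <- which(!md$diagnosis %in% c("full_ptsd", "partial_ptsd", "no_ptsd"))
  if (length(bad))
    stop("invalid diagnosis value \"", md$diagnosis[bad[1]], "\" in row ", bad[1])
  for (cc in c("crit_B", "crit_C", "crit_D", "crit_E", "crit_G"))
    md[[cc]] <- as_flag(md[[cc]], cc)
  bad <- which(md$diagnosis == "partial_ptsd" & !(md$crit_B & md$crit_G))
  if (length(bad))
    stop("row ", bad[1], ": partial_ptsd requires criteria B and G ",
         "(re-experiencing with distress/functional impairment)")
  if (anyDuplicated(md$doc_id))
    stop("duplicate doc_id in metadata")
  for (cc in intersect(c("single", "living_alone"), names(md)))
    md[[cc]] <- as_flag(md[[cc]], cc)
  md
}

as_flag <- function(x, what) {
  if (is.logical(x)) return(x)
  v <- tolower(as.character(x))
  out <- v %in% c("true", "t", "1", "yes")
  bad <- which(!v %in% c("true", "t", "1", "yes", "false", "f", "0", "no"))
  if (length(bad))
    stop("invalid value \"", x[bad[1]], "\" for flag column ", what,
         " in row ", bad[1])
  out
}

#' Read a lexicon resource
#'
#' CSV with columns `term`, `category` and optional `weight` (default 1).
#' Terms are lower-cased; a duplicated (term, category) pair is an error.
#'
#' @param path CSV file.
#' @param name Resource name; defaults to the filename stem.
#' @param match_policy Match against `"lemma"` (default) or `"surface"`.
#' @return Object of class `lf_lexicon`: data.frame (term, category, weight)
#'   with attributes `name` and `match_policy`.
#' @export
read_lexicon <- function(path, name = NULL,
                         match_policy = c("lemma", "surface")) {
  match_policy <- match.arg(match_policy)
  lx <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("term", "category") %in% names(lx)))
    stop("lexicon must have columns term, category: ", path)
  if (is.null(lx$weight)) lx$weight <- 1
  as_lexicon(lx, name = name %||% sub("\\.csv$", "", basename(path)),
             match_policy = match_policy)
}

as_lexicon <- function(df, name, match_policy = "lemma") {
  df$term <- tolower(df$term)
  df$weight <- as.numeric(df$weight)
  if (any(!is.finite(df$weight))) stop("non-finite lexicon weight")
  if (anyDuplicated(df[c("term", "category")]))
    stop("duplicate (term, category) pair in lexicon ", name)
  out <- df[c("term", "category", "weight")]
  attr(out, "name") <- name
  attr(out, "match_policy") <- match_policy
  class(out) <- c("lf_lexicon", "data.frame")
  out
}

#' Write a lexicon resource to CSV
#' @param lexicon `lf_lexicon`.
#' @param path Output CSV.
#' @export
write_lexicon <- function(lexicon, path) {
  utils::write.csv(as.data.frame(lexicon), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a document-by-feature table
#'
#' The on-disk layout mirrors a plain feature CSV: a `doc_id` column plus one
#' numeric column per registered feature, in registry order.  The round trip
#' is lossless to near machine precision (values are written with 17
#' significant digits).  Unknown feature columns are kept with a warning on
#' read.
#'
#' @param table Feature table (data.frame, `doc_id` + features).
#' @param path CSV file.
#' @param registry Registry used to order/validate columns.
#' @return `read_feature_table`: the table, class `lf_features`;
#'   `write_feature_table`: `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, TRUE)
  for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, registry = lf_registry()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        check.names = FALSE)
  if (!"doc_id" %in% names(df)) stop("feature table must have a doc_id column")
  df$doc_id <- as.character(df$doc_id)
  unknown <- setdiff(names(df), c("doc_id", registry$name))
  if (length(unknown))
    warning("unknown feature columns kept as-is: ",
            paste(unknown, collapse = ", "))
  class(df) <- c("lf_features", "data.frame")
  attr(df, "registry") <- registry
  df
}
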