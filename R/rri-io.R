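#' Write a cohort as a long-format RRI table
#'
#' One row per beat, columns `participant,group,visit,phase,beat_index,rri_ms`;
#' `beat_index` counts from 0 within each series. A `.gz` path is written
#' compressed.
#'
#' @param cohort an `hrv_cohort` (or plain list of [rri_series()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rri_table <- function(cohort, path) {
  df <- as.data.frame.hrv_cohort(cohort)
  df$rri_ms <- sprintf("%.17g", df$rri_ms)  # full precision: read o write = identity
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.hrv_cohort <- function(x, ...) {
  n_beats <- vapply(x, function(s) length(s$intervals_ms), 0L)
  data.frame(
    participant = rep(vapply(x, function(s) s$participant_id, ""), n_beats),
    group = rep(vapply(x, function(s) s$group, ""), n_beats),
    visit = rep(vapply(x, function(s) s$visit, 0L), n_beats),
    phase = rep(vapply(x, function(s) s$phase, ""), n_beats),
    beat_index = unlist(lapply(n_beats, function(n) seq_len(n) - 1L)),
    rri_ms = unlist(lapply(x, function(s) s$intervals_ms)),
    stringsAsFactors = FALSE
  )
}

#' Read a long-format RRI table into a cohort
#'
#' Inverse of [write_rri_table()]. The file must carry the header
#' `participant,group,visit,phase,beat_index,rri_ms`; rows are validated
#' (known group and phase tokens, strictly positive intervals, `beat_index`
#' contiguous from 0 within each series) and parse errors name the offending
#' row.
#'
#' @param path CSV path (plain or gzip).
#' @return An `hrv_cohort`.
#' @export
read_rri_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty RRI table: no beats in ", path, call. = FALSE)
  need <- c("participant", "group", "visit", "phase", "beat_index", "rri_ms")
  if (!all(need %in% names(df))) {
    stop("RRI table must have columns ", paste(need, collapse = ","), call. = FALSE)
  }
  bad <- which(!df$group %in% GROUPS)
  if (length(bad)) stop("unknown group token '", df$group[bad[1]], "' at row ", bad[1], call. = FALSE)
  bad <- which(!df$phase %in% PHASES)
  if (length(bad)) stop("unknown phase token '", df$phase[bad[1]], "' at row ", bad[1], call. = FALSE)
  bad <- which(!is.finite(df$rri_ms) | df$rri_ms <= 0)
  if (length(bad)) stop("non-positive RR interval at row ", bad[1], call. = FALSE)
  key <- paste(df$participant, df$visit, df$phase, sep = "\r")
  idx <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  series <- lapply(idx, function(i) {
    i <- i[order(df$beat_index[i])]
    bi <- df$beat_index[i]
    if (!identical(as.integer(bi), seq_along(bi) - 1L)) {
      gap <- i[which(as.integer(bi) != seq_along(bi) - 1L)[1]]
      stop("beat_index not contiguous from 0 near row ", gap, call. = FALSE)
    }
    rri_series(df$participant[i[1]], df$group[i[1]], df$visit[i[1]],
               df$phase[i[1]], df$rri_ms[i])
  })
  names(series) <- NULL
  new_cohort(series)
}
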