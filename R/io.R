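#' Read per-subject trial logs from delimited text
#'
#' Canonical schema: one row per trial with columns subject_id, trial,
#' choice1 (0/1), state2 (1/2), choice2 (0/1), outcome (0/1) and optionally
#' transition (0 rare / 1 common), which is recomputed from (choice1,
#' state2) against the configured true structure when absent. A
#' `column_map` renames nonstandard headers (names = canonical, values =
#' file headers).
#'
#' @param path CSV file path.
#' @param column_map optional named character vector mapping canonical
#'   column names to the file's headers.
#' @param config a [task_config()] recording the true transition structure
#'   and outcome valence for the dataset.
#' @return named list of `twostep_session` objects, one per subject.
#' @export
read_trials <- function(path, column_map = NULL, config = task_config()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) {
        stop("mapped column not found: ", src, call. = FALSE)
      }
      names(df)[names(df) == src] <- canon
    }
  }
  required <- c("subject_id", "trial", "choice1", "state2", "choice2",
                "outcome")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  check_domain <- function(col, allowed) {
    bad <- which(!df[[col]] %in% allowed)
    if (length(bad) > 0) {
      stop(sprintf("invalid %s value %s at row %d", col,
                   df[[col]][bad[1]], bad[1]), call. = FALSE)
    }
  }
  check_domain("choice1", c(0L, 1L))
  check_domain("choice2", c(0L, 1L))
  check_domain("state2", c(1L, 2L))
  check_domain("outcome", c(0L, 1L))
  p_true <- true_transition_matrix(config)
  common_state <- apply(p_true, 1, which.max)
  sessions <- lapply(split(df, df$subject_id), function(d) {
    d <- d[order(d$trial), ]
    a1 <- d$choice1 + 1L
    s2 <- d$state2
    tr <- if ("transition" %in% names(d)) {
      as.integer(d$transition)
    } else {
      as.integer(s2 == common_state[a1])
    }
    cfg <- config
    cfg$n_trials <- nrow(d)
    new_session(cfg,
                data.frame(t = seq_len(nrow(d)), a1 = a1, s2 = s2,
                           transition = tr, a2 = d$choice2 + 1L,
                           o = as.integer(d$outcome)),
                subject_id = d$subject_id[1])
  })
  sessions
}

#' Write sessions to the canonical CSV trial schema
#'
#' @param sessions named list of `twostep_session` objects (names used as
#'   subject ids when the sessions carry none).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_trials <- function(sessions, path) {
  rows <- lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    id <- s$subject_id
    if (is.null(id) || is.na(id)) id <- names(sessions)[i] %||% i
    data.frame(subject_id = id, trial = s$trials$t,
               choice1 = s$trials$a1 - 1L, state2 = s$trials$s2,
               choice2 = s$trials$a2 - 1L, outcome = s$trials$o,
               transition = s$trials$transition)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write analysis results to JSON or CSV
#'
#' `twostep_fit` and `bms_result` objects and coefficient tables
#' round-trip losslessly through JSON (full numeric precision); data
#' frames may also be written as CSV by extension.
#'
#' @param object a `twostep_fit`, `bms_result`, data frame, or plain list
#'   of numeric fields.
#' @param path output path ending in .json or .csv.
#' @return the path, invisibly.
#' @export
write_results <- function(object, path) {
  if (grepl("\\.csv$", path)) {
    if (!is.data.frame(object)) {
      stop("CSV output requires a data frame", call. = FALSE)
    }
    utils::write.csv(object, path, row.names = FALSE)
    return(invisible(path))
  }
  x <- serialise_result(object)
  stopifnot_nan_free(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back results written by [write_results()]
#'
#' @param path JSON path.
#' @return list with the stored fields.
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

serialise_result <- function(object) {
  if (inherits(object, "twostep_fit")) {
    list(class = "twostep_fit", model_id = object$model_id,
         subject_id = object$subject_id, params = as.list(object$params),
         logLik = object$logLik, aic = object$aic, bic = object$bic,
         k = object$k, n_trials = object$n_trials,
         n_restarts = object$n_restarts, seed = object$seed)
  } else if (inherits(object, "bms_result")) {
    out <- list(class = "bms_result", alpha = as.list(object$alpha),
                expected_r = as.list(object$expected_r),
                xp = as.list(object$xp), pxp = as.list(object$pxp),
                bor = object$bor)
    if (!is.null(object$family_xp)) {
      out$family_expected_r <- as.list(object$family_expected_r)
      out$family_xp <- as.list(object$family_xp)
    }
    out
  } else if (is.matrix(object)) {
    list(class = "matrix", dimnames = dimnames(object),
         values = as.vector(object), nrow = nrow(object))
  } else {
    object
  }
}

stopifnot_nan_free <- function(x) {
  vals <- unlist(x, use.names = FALSE)
  num <- suppressWarnings(as.numeric(vals[!is.na(suppressWarnings(
    as.numeric(vals)))]))
  if (any(is.nan(num))) stop("NaN in results output", call. = FALSE)
  invisible(TRUE)
}
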