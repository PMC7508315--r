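#' Message pool with non-repetitive selection
#'
#' A pool stores interchangeable phrasings of prompts or one-way health tips,
#' grouped into topical subsets, and serves them so that no patient sees the
#' same message twice before the whole pool has cycled. Selection walks a
#' per-patient random permutation of the pool; when the permutation is
#' exhausted it reshuffles, never letting the first message of the new cycle
#' repeat the last message of the old one (unless the pool has a single
#' message). Selection uses R's RNG, so a `set.seed()` upstream makes the
#' sequence reproducible.
#'
#' @param subsets Named list of character vectors (subset name -> messages).
#'   Every subset must be non-empty and free of duplicate texts.
#' @param pool_id Identifier for error messages and logs.
#' @return An object of class `txt_pool`.
#' @export
message_pool <- function(subsets, pool_id = "pool") {
  if (length(subsets) == 0L) abort("a pool needs at least one subset")
  if (is.null(names(subsets)) || any(!nzchar(names(subsets)))) {
    abort("every subset must be named")
  }
  for (nm in names(subsets)) {
    msgs <- subsets[[nm]]
    if (length(msgs) == 0L) {
      abort(sprintf("subset '%s' is empty", nm))
    }
    if (anyDuplicated(msgs)) {
      abort(sprintf("subset '%s' contains duplicate messages", nm))
    }
  }
  structure(list(pool_id = pool_id, subsets = subsets,
                 messages = unname(unlist(subsets)),
                 history = list()),
            class = "txt_pool")
}

#' @export
print.txt_pool <- function(x, ...) {
  cat(sprintf("<txt_pool '%s'> %d messages in %d subsets\n",
              x$pool_id, length(x$messages), length(x$subsets)))
  invisible(x)
}

#' @rdname message_pool
#' @export
pool_size <- function(pool) length(pool$messages)

#' Select the next message for a patient
#'
#' @param pool A [message_pool()].
#' @param patient_id Patient the message is addressed to (selection history
#'   is tracked per patient).
#' @return List with `text` (the chosen message) and `pool` (the pool with
#'   updated history; reassign it, the structure is immutable).
#' @export
pool_select <- function(pool, patient_id) {
  stopifnot(inherits(pool, "txt_pool"))
  n <- length(pool$messages)
  st <- pool$history[[patient_id]] %||% list(remaining = integer(),
                                             last = NA_integer_)
  if (length(st$remaining) == 0L) {
    perm <- sample.int(n)
    if (n > 1L && !is.na(st$last) && perm[1] == st$last) {
      j <- if (n == 2L) 2L else sample(2:n, 1L)
      perm[c(1L, j)] <- perm[c(j, 1L)]
    }
    st$remaining <- perm
  }
  idx <- st$remaining[1]
  st$remaining <- st$remaining[-1]
  st$last <- idx
  pool$history[[patient_id]] <- st
  list(text = pool$messages[idx], pool = pool)
}

#' Load a message pool from a plain-text file
#'
#' The file format is UTF-8 text with `[subset-name]` section headers and one
#' message per line; blank lines and `#` comment lines are ignored. A
#' synthetic health-tip pool with 11 subsets and 54 messages ships at
#' `system.file("extdata", "pools", "health_tips.txt", package = "txtpro")`.
#'
#' @param path Pool file path.
#' @param pool_id Identifier; defaults to the file name.
#' @return A [message_pool()].
#' @export
read_pool <- function(path, pool_id = tools::file_path_sans_ext(basename(path))) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  subsets <- list()
  current <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      current <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (current %in% names(subsets)) {
        abort(sprintf("subset '%s' declared twice in %s", current, path))
      }
      subsets[[current]] <- character()
    } else {
      if (is.null(current)) {
        abort(sprintf("message before any [subset] header in %s", path))
      }
      subsets[[current]] <- c(subsets[[current]], ln)
    }
  }
  message_pool(subsets, pool_id = pool_id)
}
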