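# Item banks hold the assignments each exercise draws from: one table per
# exercise type, plus generated roadmap grids. Banks are plain structured
# text on disk (TSV per exercise, JSON for roadmaps) so therapists can
# curate them without touching code.

# pseudo-word generator for fixture stimuli: CVCV(CV) strings
make_word <- function(n_letters = 5L) {
  cons <- strsplit("bcdfghklmnprstvz", "")[[1]]
  vow <- strsplit("aeiou", "")[[1]]
  paste(vapply(seq_len(n_letters), function(i) {
    if (i %% 2 == 1) sample(cons, 1L) else sample(vow, 1L)
  }, character(1)), collapse = "")
}

#' Generate fixture item banks for all 11 exercises
#'
#' Produces syntactically valid, solvable item banks for every exercise
#' type: keyed items for the generic exercises, guess words with taboo-word
#' triples for Tabooword, picture-pair metadata with balanced
#' same/different ground-truth labels for Differences, and roadmap grids
#' with seven locations and a reachable destination (verified by
#' breadth-first search) for Roadmap. These banks stand in for the curated
#' assignments of a clinical deployment and carry no linguistic content:
#' stimuli are pseudo-words and opaque ids.
#'
#' @param n_items Items generated per exercise and per level (default 12).
#' @return A named list of class `dt_banks`: one data frame per non-map
#'   exercise and, under `ROADMAP`, a list of `dt_roadmap` maps with a
#'   `level` attribute each.
#' @examples
#' set.seed(11)
#' banks <- generate_fixture_banks(n_items = 4)
#' names(banks)
#' @export
generate_fixture_banks <- function(n_items = 12L) {
  n_items <- check_int_range(n_items, 0L, 10000L, "n_items")
  banks <- list()
  for (ex in exercise_catalog()$exercise) {
    if (ex == "ROADMAP") {
      banks[[ex]] <- if (n_items == 0L) list() else
        unlist(lapply(1:3, function(lv) {
          lapply(seq_len(n_items), function(i) generate_roadmap(lv))
        }), recursive = FALSE)
      next
    }
    if (n_items == 0L) {
      banks[[ex]] <- data.frame()
      next
    }
    rows <- lapply(1:3, function(lv) generate_bank_items(ex, lv, n_items))
    banks[[ex]] <- do.call(rbind, rows)
  }
  structure(banks, class = "dt_banks")
}

generate_bank_items <- function(exercise, level, n) {
  id <- sprintf("%s-L%d-%03d", exercise, level, seq_len(n))
  base <- data.frame(id = id, level = level, stringsAsFactors = FALSE)
  switch(
    exercise,
    NOISE = {
      k <- level_parameters("NOISE", level)$n_targets
      base$stimulus <- vapply(seq_len(n), function(i)
        paste0("noise_set_", sample(1e4, 1L)), character(1))
      base$key <- vapply(seq_len(n), function(i)
        paste0("target_", sample(k, 1L)), character(1))
      base
    },
    WORDS = {
      rule <- sample(c("first", "last", "second", "fourth"), n,
                     replace = TRUE)
      word <- vapply(seq_len(n), function(i) make_word(5L + level),
                     character(1))
      pos <- c(first = 1L, last = NA_integer_, second = 2L, fourth = 4L)
      base$stimulus <- paste(rule, word, sep = ":")
      base$key <- vapply(seq_len(n), function(i) {
        p <- if (rule[i] == "last") nchar(word[i]) else pos[[rule[i]]]
        substr(word[i], p, p)
      }, character(1))
      base
    },
    APPLE = {
      base$stimulus <- vapply(seq_len(n), function(i) make_word(5L),
                              character(1))
      base$key <- sample(c("yes", "no"), n, replace = TRUE)
      base
    },
    REVERSE = {
      # three- to seven-or-more-letter words, longer at higher levels
      word <- vapply(seq_len(n), function(i)
        make_word(sample((2L + level):(4L + level), 1L)), character(1))
      base$stimulus <- word
      base$key <- vapply(strsplit(word, ""), function(ch)
        paste(rev(ch), collapse = ""), character(1))
      base
    },
    LISTEN = {
      base$stimulus <- vapply(seq_len(n), function(i) make_word(5L),
                              character(1))
      base$key <- sample(c("heard", "new"), n, replace = TRUE)
      base
    },
    TABOOWORD = {
      base$stimulus <- vapply(seq_len(n), function(i) make_word(6L),
                              character(1))
      base$taboo_words <- vapply(seq_len(n), function(i)
        paste(replicate(3L, make_word(5L)), collapse = ","), character(1))
      base$key <- "description"  # scored by the therapist, not by key
      base
    },
    STORY = {
      base$stimulus <- sprintf("story_%s", base$id)
      keys <- replicate(n, paste(sample(c("a", "b", "c"), 3L,
                                        replace = TRUE), collapse = ","))
      base$key <- keys
      base
    },
    DIFFERENCES = {
      # balanced same/different labels
      lab <- sample(rep_len(c(TRUE, FALSE), n))
      base$stimulus <- sprintf("pair_%s", base$id)
      base$is_same <- lab
      base$key <- ifelse(lab, "same", "different")
      base
    },
    SEE = {
      base$stimulus <- sprintf("smiley_%s", base$id)
      base$key <- sample(c("1", "2", "3"), n, replace = TRUE)
      base
    },
    THINK = {
      base$stimulus <- sprintf("puzzle_%s", base$id)
      base$key <- sample(c("a", "b", "c", "d"), n, replace = TRUE)
      base
    },
    stop("unknown exercise: ", exercise, call. = FALSE)
  )
}

# Random solvable roadmap at a given difficulty level. Level 3 adds
# one-way streets; generation retries until the destination stays
# reachable (always succeeds quickly on a 5x5 grid).
generate_roadmap <- function(level = 1L) {
  level <- check_int_range(level, 1L, 3L, "level")
  nrow <- 5L; ncol <- 5L
  params <- level_parameters("ROADMAP", level)
  repeat {
    cells <- sample.int(nrow * ncol, 8L)
    locs <- setNames(cells[1:7],
                     c("butcher", "park", "school", "bakery", "church",
                       "station", "pharmacy"))
    start <- cells[8L]
    one_way <- NULL
    if (params$one_way) {
      ow <- lapply(seq_len(4L), function(i) {
        r <- sample.int(nrow, 1L); c <- sample.int(ncol - 1L, 1L)
        from <- (r - 1L) * ncol + c
        c(from = from, to = from + 1L)
      })
      one_way <- as.data.frame(do.call(rbind, ow))
    }
    m <- tryCatch(
      roadmap_map(nrow, ncol, locs, start,
                  sample(HEADINGS, 1L),
                  destination = sample(names(locs), 1L),
                  one_way = one_way,
                  distractors = params$distractors),
      error = function(e) NULL
    )
    if (!is.null(m)) {
      attr(m, "level") <- level
      return(m)
    }
  }
}

#' Write and read item banks
#'
#' Banks are persisted one file per exercise under a directory: TSV for
#' tabular banks, JSON for the roadmap grids.
#'
#' @param banks A `dt_banks` list.
#' @param dir Directory (created if needed).
#' @return `write_banks()` returns `dir` invisibly; `read_banks()` returns
#'   a `dt_banks`. An empty bank file for an exercise makes `read_banks()`
#'   raise a configuration error naming the exercise.
#' @export
write_banks <- function(banks, dir) {
  stopifnot(inherits(banks, "dt_banks"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ex in names(banks)) {
    if (ex == "ROADMAP") {
      maps <- lapply(banks[[ex]], function(m) {
        list(nrow = m$nrow, ncol = m$ncol,
             locations = as.list(m$locations),
             start_cell = m$start_cell, start_heading = m$start_heading,
             destination = m$destination,
             one_way = m$one_way, distractors = m$distractors,
             level = attr(m, "level") %||% 1L)
      })
      jsonlite::write_json(maps, file.path(dir, "ROADMAP.json"),
                           auto_unbox = TRUE, digits = NA)
    } else {
      utils::write.table(banks[[ex]], file.path(dir, paste0(ex, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname write_banks
#' @export
read_banks <- function(dir) {
  stopifnot(dir.exists(dir))
  banks <- list()
  for (ex in exercise_catalog()$exercise) {
    if (ex == "ROADMAP") {
      path <- file.path(dir, "ROADMAP.json")
      if (!file.exists(path)) {
        stop("configuration error: missing bank file for ROADMAP",
             call. = FALSE)
      }
      raw <- jsonlite::read_json(path)
      if (!length(raw)) {
        stop("configuration error: empty bank for ROADMAP", call. = FALSE)
      }
      banks[[ex]] <- lapply(raw, function(x) {
        ow <- NULL
        if (!is.null(x$one_way) && length(x$one_way)) {
          ow <- do.call(rbind, lapply(x$one_way, function(e)
            data.frame(from = e$from, to = e$to)))
        }
        m <- roadmap_map(x$nrow, x$ncol,
                         setNames(as.integer(unlist(x$locations)),
                                  names(x$locations)),
                         x$start_cell, x$start_heading, x$destination,
                         one_way = ow,
                         distractors = unlist(x$distractors) %||%
                           character(0))
        attr(m, "level") <- x$level %||% 1L
        m
      })
    } else {
      path <- file.path(dir, paste0(ex, ".tsv"))
      if (!file.exists(path)) {
        stop("configuration error: missing bank file for ", ex,
             call. = FALSE)
      }
      df <- utils::read.delim(path, stringsAsFactors = FALSE,
                              colClasses = "character")
      if (!nrow(df)) {
        stop("configuration error: empty bank for ", ex, call. = FALSE)
      }
      df$level <- as.integer(df$level)
      if ("is_same" %in% names(df)) df$is_same <- as.logical(df$is_same)
      banks[[ex]] <- df
    }
  }
  structure(banks, class = "dt_banks")
}

# Draw n items of one exercise at a level (with replacement if the bank
# is smaller than n). Roadmaps return map objects.
draw_bank_items <- function(banks, exercise, level, n) {
  bank <- banks[[exercise]]
  if (is.null(bank) || (is.data.frame(bank) && !nrow(bank)) ||
      (!is.data.frame(bank) && !length(bank))) {
    stop("configuration error: empty bank for ", exercise, call. = FALSE)
  }
  if (exercise == "ROADMAP") {
    lv <- vapply(bank, function(m) attr(m, "level") %||% 1L, numeric(1))
    pool <- bank[lv == level]
    if (!length(pool)) pool <- bank
    pool[sample.int(length(pool), n, replace = TRUE)]
  } else {
    pool <- bank[bank$level == level, , drop = FALSE]
    if (!nrow(pool)) pool <- bank
    pool[sample.int(nrow(pool), n, replace = TRUE), , drop = FALSE]
  }
}
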