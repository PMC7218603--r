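#' The training exercise catalog
#'
#' Eleven cognitive exercises train twelve cognitive functions in dual-task
#' mode. The seven auditory exercises (Noise, Words, Apple, Reverse,
#' Listen, Tabooword, Story) are performed while walking; the four visual
#' exercises (Differences, See, Think, Roadmap) while stepping on the spot.
#' Words and Reverse each train both working memory and information
#' processing speed; Think trains both verbal and visual analog reasoning.
#'
#' @return Data frame with columns `exercise`, `motor_mode` (`"walking"` or
#'   `"stepping"`), and `functions` (list column of cognitive function
#'   tags).
#' @examples
#' nrow(exercise_catalog())                       # 11 exercises
#' length(cognitive_functions())                  # 12 functions
#' @export
exercise_catalog <- function() {
  cat <- data.frame(
    exercise = c("NOISE", "WORDS", "APPLE", "REVERSE", "LISTEN",
                 "TABOOWORD", "STORY",
                 "DIFFERENCES", "SEE", "THINK", "ROADMAP"),
    motor_mode = c(rep("walking", 7L), rep("stepping", 4L)),
    stringsAsFactors = FALSE
  )
  cat$functions <- list(
    "auditory_discrimination",
    c("working_memory", "information_processing_speed"),
    "sustained_attention",
    c("working_memory", "information_processing_speed"),
    "auditory_memory",
    "verbal_fluency",
    "text_comprehension",
    "visual_discrimination",
    "visual_memory",
    c("verbal_analog_reasoning", "visual_analog_reasoning"),
    "visual_spatial_planning"
  )
  cat
}

#' @rdname exercise_catalog
#' @export
cognitive_functions <- function() {
  sort(unique(unlist(exercise_catalog()$functions)))
}

#' Per-level exercise parameters
#'
#' Difficulty levels 1-3 change timing and distractor load. Tabooword:
#' 20 s / no taboo words at level 1, 30 s / 1 at level 2, 40 s / 3 at
#' level 3. Differences: 15 / 20 / 30 s to judge picture equality (the
#' pictures also get harder: several differences, one difference, one
#' small difference). Roadmap: level 1 has no map distractors and a
#' heading icon; level 2 adds roundabouts, houses and trees with a dot
#' icon; level 3 additionally adds one-way streets. Exercises without
#' printed per-level timing use a common default item time limit.
#'
#' @param exercise Exercise id from [exercise_catalog()].
#' @param level Difficulty level 1, 2 or 3.
#' @return Named list of parameters for the exercise at that level.
#' @examples
#' level_parameters("TABOOWORD", 3)  # 40 s, 3 taboo words
#' @export
level_parameters <- function(exercise, level) {
  level <- check_int_range(level, 1L, 3L, "level")
  exercise <- match.arg(exercise, exercise_catalog()$exercise)
  switch(
    exercise,
    TABOOWORD = list(
      time_limit_s = c(20, 30, 40)[level],
      n_taboo_words = c(0L, 1L, 3L)[level]
    ),
    DIFFERENCES = list(
      time_limit_s = c(15, 20, 30)[level],
      difference_descriptor = c("more than one difference",
                                "one difference",
                                "one small difference")[level]
    ),
    ROADMAP = list(
      distractors = switch(level,
                           character(0),
                           c("roundabouts", "houses", "trees"),
                           c("roundabouts", "houses", "trees",
                             "one_way_streets")),
      indicator = if (level == 1L) "head" else "dot",
      one_way = level == 3L
    ),
    NOISE = list(
      # target count scales with difficulty within the printed 2-4 range
      n_targets = c(2L, 3L, 4L)[level],
      time_limit_s = 15
    ),
    # remaining exercises: a common item time limit; difficulty is carried
    # by the item bank's per-level stimuli
    list(time_limit_s = 15)
  )
}
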