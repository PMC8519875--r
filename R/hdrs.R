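#' @title HDRS-17 item metadata
#' @description Canonical 17-item Hamilton Depression Rating Scale item
#'   table: standard ordering, item names (the join key used in all I/O,
#'   to avoid numbering-dialect bugs), and legal score ranges. Items 1
#'   (depressed mood), 2 (guilt), 3 (suicide), 7 (work and interests), 8
#'   (retardation), 9 (agitation), 10 (psychic anxiety), 11 (somatic
#'   anxiety) and 15 (hypochondriasis) are scored 0-4; the remainder 0-2.
#' @format data.frame with columns `number`, `name`, `max`.
#' @export
hdrs_items <- data.frame(
  number = 1:17,
  name = c("depressed_mood", "guilt", "suicide", "insomnia_early",
           "insomnia_middle", "insomnia_late", "work_and_interests",
           "retardation", "agitation", "psychic_anxiety", "somatic_anxiety",
           "somatic_gastrointestinal", "general_somatic", "genital_symptoms",
           "hypochondriasis", "weight_loss", "insight"),
  max = c(4L, 4L, 4L, 2L, 2L, 2L, 4L, 4L, 4L, 4L, 4L, 2L, 2L, 2L, 4L, 2L, 2L),
  stringsAsFactors = FALSE
)

#' @title Latent symptom-dimension item sets
#' @description Fixed item-to-dimension mapping from the prior exploratory
#'   factor analysis of pretreatment HDRS-17 items: somatic disturbances
#'   (`sod`, 8 items), core mood and anhedonia (`cma`, 4 items), and
#'   `insomnia` (3 items). The suicide and insight items load on no
#'   dimension and contribute only to the HDRS-17 total. `hdrs6` is the
#'   Bech melancholia subscale used as a benchmark outcome.
#' @format named list of character vectors of item names.
#' @export
hdrs_dimensions <- list(
  sod = c("somatic_gastrointestinal", "hypochondriasis", "guilt",
          "genital_symptoms", "general_somatic", "somatic_anxiety",
          "psychic_anxiety", "agitation"),
  cma = c("work_and_interests", "weight_loss", "retardation",
          "depressed_mood"),
  insomnia = c("insomnia_early", "insomnia_middle", "insomnia_late"),
  hdrs6 = c("depressed_mood", "guilt", "work_and_interests", "retardation",
            "psychic_anxiety", "general_somatic")
)

# Partition guard: the three dimensions plus the two omitted items must
# tile the 17 items exactly (checked once at build time, not per call).
local({
  parts <- c(hdrs_dimensions$sod, hdrs_dimensions$cma,
             hdrs_dimensions$insomnia, "suicide", "insight")
  stopifnot(!anyDuplicated(parts), setequal(parts, hdrs_items$name))
})

#' Maximum attainable score per scale
#'
#' Sums of per-item maxima over each scale's item set: SoD 26, CMA 14,
#' insomnia 6, HDRS-6 22, HDRS-17 52.
#'
#' @return named integer vector.
#' @export
dimension_maxima <- function() {
  mx <- stats::setNames(hdrs_items$max, hdrs_items$name)
  c(sod = sum(mx[hdrs_dimensions$sod]),
    cma = sum(mx[hdrs_dimensions$cma]),
    insomnia = sum(mx[hdrs_dimensions$insomnia]),
    hdrs6_total = sum(mx[hdrs_dimensions$hdrs6]),
    hdrs17_total = sum(mx))
}

validate_hdrs_items <- function(items) {
  if (is.data.frame(items)) items <- unlist(items[1, , drop = TRUE])
  if (is.null(names(items)) && length(items) == 17L) {
    names(items) <- hdrs_items$name  # positional fallback, standard order
  }
  missing <- setdiff(hdrs_items$name, names(items))
  if (length(missing) > 0)
    stop("missing HDRS item(s): ", paste(missing, collapse = ", "))
  items <- items[hdrs_items$name]
  bad <- which(is.na(items) | items < 0 | items > hdrs_items$max |
                 items != round(items))
  if (length(bad) > 0)
    stop("HDRS item(s) out of range: ",
         paste0(hdrs_items$name[bad], "=", items[bad], collapse = ", "))
  items
}

#' Score an HDRS-17 assessment into symptom dimensions
#'
#' Computes the three latent dimension scores (unit-weight sums over each
#' dimension's item set by default) plus the HDRS-6 and HDRS-17 benchmark
#' totals. The suicide and insight items enter only the HDRS-17 total.
#'
#' @param items named numeric vector of the 17 item scores, keyed by the
#'   names in [hdrs_items] (an unnamed length-17 vector is taken in
#'   standard item order); or a one-row data.frame of the same.
#' @param weights optional named list mapping scale name (`sod`, `cma`,
#'   `insomnia`, `hdrs6`) to a named numeric vector of per-item weights;
#'   defaults to unit weights (sum scores).
#' @return named numeric vector with elements `sod`, `cma`, `insomnia`,
#'   `hdrs6_total`, `hdrs17_total`.
#' @examples
#' score_dimensions(rep(1, 17))  # sod 8, cma 4, insomnia 3, total 17
#' @export
score_dimensions <- function(items, weights = NULL) {
  items <- validate_hdrs_items(items)
  wsum <- function(scale, set) {
    w <- rep(1, length(set))
    names(w) <- set
    if (!is.null(weights) && !is.null(weights[[scale]])) {
      user <- weights[[scale]]
      w[names(user)] <- user
    }
    sum(items[set] * w)
  }
  c(sod = wsum("sod", hdrs_dimensions$sod),
    cma = wsum("cma", hdrs_dimensions$cma),
    insomnia = wsum("insomnia", hdrs_dimensions$insomnia),
    hdrs6_total = wsum("hdrs6", hdrs_dimensions$hdrs6),
    hdrs17_total = sum(items))
}

#' Change score between two scored assessments
#'
#' Post-treatment minus baseline on each of the five scales; negative
#' values indicate symptom improvement.
#'
#' @param pre,post outputs of [score_dimensions()] for the same subject.
#' @return named numeric vector of signed changes.
#' @export
change_score <- function(pre, post) {
  nm <- c("sod", "cma", "insomnia", "hdrs6_total", "hdrs17_total")
  stopifnot(all(nm %in% names(pre)), all(nm %in% names(post)))
  post[nm] - pre[nm]
}

#' Score every subject in a cohort table
#'
#' Applies [score_dimensions()] to the `hdrs_pre_01..17` and
#' `hdrs_post_01..17` columns of a cohort table and returns baseline, post,
#' and change scores for all five scales.
#'
#' @param cohort cohort data.frame as produced by [generate_cohort()] or
#'   [read_cohort()].
#' @param weights passed through to [score_dimensions()].
#' @return list with data.frames `baseline`, `post`, `change` (one row per
#'   subject, rownames = subject ids).
#' @export
score_cohort <- function(cohort, weights = NULL) {
  pre_cols <- sprintf("hdrs_pre_%02d", 1:17)
  post_cols <- sprintf("hdrs_post_%02d", 1:17)
  stopifnot(all(pre_cols %in% names(cohort)),
            all(post_cols %in% names(cohort)))
  score_block <- function(cols) {
    m <- as.matrix(cohort[, cols])
    colnames(m) <- hdrs_items$name
    out <- t(apply(m, 1, score_dimensions, weights = weights))
    rownames(out) <- cohort$id
    as.data.frame(out)
  }
  baseline <- score_block(pre_cols)
  post <- score_block(post_cols)
  list(baseline = baseline, post = post, change = post - baseline)
}
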