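#' Label code for one field's masking level
#'
#' Each masking level is encoded as an integer label: the feature value
#' the surrogate models learn from and the input to the usability rule.
#' For name, age and phone the two digits of the code encode (number of
#' masked characters, number of exposed characters): name 0/1/2/3 masked
#' -> 03/12/21/30; age -> 02/11/20; phone none/partial/full -> 08/17/80.
#' Categorical fields are 1 when kept and 0 when fully masked.
#'
#' @param field One of `"name"`, `"age"`, `"phone"`, `"blood"`,
#'   `"region"`, `"illness"`, `"smoking"`.
#' @param level The field's policy level: an integer for name/age, a
#'   string for phone, a logical mask flag for the categoricals.
#' @return The integer label code.
#' @export
#' @examples
#' label_code("phone", "full")  # 80
#' label_code("name", 1)        # 12
label_code <- function(field, level) {
  field <- match.arg(field, c("name", "age", "phone", "blood", "region",
                              "illness", "smoking"))
  pick <- function(codes, i) {
    if (is.na(i) || i < 1L || i > length(codes)) {
      stop("unknown masking level for field '", field, "'", call. = FALSE)
    }
    unname(codes[i])
  }
  switch(field,
    name = pick(c(3L, 12L, 21L, 30L), as.integer(level) + 1L),
    age = pick(c(2L, 11L, 20L), as.integer(level) + 1L),
    phone = pick(c(none = 8L, partial = 17L, full = 80L),
                 match(level, c("none", "partial", "full"))),
    {
      if (!is.logical(level) || length(level) != 1L || is.na(level)) {
        stop("unknown masking level for field '", field, "'", call. = FALSE)
      }
      if (level) 0L else 1L
    })
}

#' Convert a masking policy to its label codes
#'
#' @param policy A `deid_policy`.
#' @return A named integer vector of class `deid_labels` with entries
#'   `name`, `age`, `phone`, `blood`, `region`, `illness`, `smoking`.
#' @export
#' @examples
#' label_policy(masking_policy(name_level = 1, age_level = 1,
#'                             phone_level = "partial", illness_mask = TRUE))
label_policy <- function(policy) {
  stopifnot(inherits(policy, "deid_policy"))
  structure(
    c(name = label_code("name", policy$name_level),
      age = label_code("age", policy$age_level),
      phone = label_code("phone", policy$phone_level),
      blood = label_code("blood", policy$blood_mask),
      region = label_code("region", policy$region_mask),
      illness = label_code("illness", policy$illness_mask),
      smoking = label_code("smoking", policy$smoking_mask)),
    class = "deid_labels"
  )
}

#' Data usability of a labeled policy
#'
#' The usability score is computed from the label codes alone: for name,
#' age and phone the contribution is the product of the code's tens and
#' ones digits; the four categorical codes contribute their face value
#' (0 or 1). Note the quirk this digit-product rule implies: fully
#' unmasked name (03) and phone (08) contribute 0, so the attainable
#' maximum over the whole policy space is 14.
#'
#' @param labels A `deid_labels` vector (from [label_policy()]) or any
#'   named numeric vector with the seven field entries.
#' @return Integer usability score.
#' @export
#' @examples
#' pol <- masking_policy(name_level = 1, age_level = 1,
#'                       phone_level = "partial", illness_mask = TRUE)
#' usability(label_policy(pol))  # 13
usability <- function(labels) {
  labels <- unlist(labels)
  need <- c("name", "age", "phone", "blood", "region", "illness", "smoking")
  if (!all(need %in% names(labels))) {
    stop("labels must contain entries ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lab <- as.integer(labels[need])
  digits <- lab[1:3]
  as.integer(sum((digits %/% 10L) * (digits %% 10L)) + sum(lab[4:7]))
}

#' Number of deduplicated groups in a masked cohort
#'
#' Counts the distinct 7-field masked tuples: rows that are identical on
#' every masked field form one group ("the data remaining when one copy
#' of each fully redundant row is kept").
#'
#' @param masked A masked cohort data.frame from [apply_policy()].
#' @return Integer number of distinct rows.
#' @export
distinct_groups <- function(masked) {
  if (is.null(nrow(masked)) || nrow(masked) == 0L) {
    stop("masked cohort is empty", call. = FALSE)
  }
  key <- do.call(paste, c(unname(as.list(masked)), sep = "\r"))
  length(unique(key))
}

#' Data confidentiality percentage
#'
#' The fraction of original rows that remain distinguishable after
#' masking: `distinct_groups(masked) / n_original * 100`. Lower values
#' mean more rows collapsed together, i.e. individuals are harder to
#' single out.
#'
#' @param masked A masked cohort data.frame.
#' @param n_original Number of rows of the original cohort.
#' @return Percentage in `(0, 100]`.
#' @export
confidentiality_pct <- function(masked, n_original) {
  if (length(n_original) != 1L || is.na(n_original) || n_original <= 0) {
    stop("n_original must be a positive count", call. = FALSE)
  }
  distinct_groups(masked) / n_original * 100
}

#' Interval score for a confidentiality percentage
#'
#' Maps the percentage to the banded score used in the final score:
#' `(0,20] -> 15`, `(20,40] -> 12`, `(40,60] -> 9`, `(60,80] -> 6`,
#' `(80,99) -> 3`, `[99,100) -> 1`, and exactly 100 -> 0 (no row
#' collapsed at all: the de-identification did nothing). The bands step
#' by 3 so the score shares the 0--15 range of the usability scale.
#'
#' @param pct Percentage in `(0, 100]`.
#' @return Integer in `{0, 1, 3, 6, 9, 12, 15}`.
#' @export
#' @examples
#' confidentiality_value(20)   # 15
#' confidentiality_value(50)   # 9
#' confidentiality_value(100)  # 0
confidentiality_value <- function(pct) {
  if (length(pct) != 1L || is.na(pct) || pct <= 0 || pct > 100) {
    stop("pct must lie in (0, 100]", call. = FALSE)
  }
  if (pct == 100) return(0L)
  if (pct >= 99) return(1L)
  if (pct > 80) return(3L)
  if (pct > 60) return(6L)
  if (pct > 40) return(9L)
  if (pct > 20) return(12L)
  15L
}

#' Score a (cohort, policy) pair
#'
#' Computes the full score breakdown: usability from the policy's label
#' codes, the deduplication-based confidentiality percentage of the
#' masked cohort, its interval score, and the final score (usability +
#' confidentiality interval score) — the dependent variable the
#' surrogate models are trained to predict.
#'
#' @param cohort A cohort data.frame.
#' @param policy A `deid_policy`.
#' @return An object of class `deid_score`: a list with elements
#'   `usability`, `confidentiality_pct`, `confidentiality_value`,
#'   `final_score`, and the policy's `labels`.
#' @export
#' @examples
#' cohort <- generate_cohort(100, seed = 1)
#' score_policy(cohort, masking_policy(name_level = 3, age_level = 2,
#'                                     phone_level = "full"))
score_policy <- function(cohort, policy) {
  labels <- label_policy(policy)
  u <- usability(labels)
  pct <- confidentiality_pct(apply_policy(cohort, policy), nrow(cohort))
  cv <- confidentiality_value(pct)
  final_score(u, pct, cv, labels)
}

#' Assemble a score breakdown
#'
#' Combines an already-computed usability score and confidentiality
#' percentage into the final score. Normally called via [score_policy()].
#'
#' @param usability Integer usability score.
#' @param confidentiality_pct Percentage in `(0, 100]`.
#' @param confidentiality_value Optional banded score; recomputed from
#'   the percentage when omitted.
#' @param labels Optional `deid_labels` attached for reporting.
#' @return A `deid_score` object.
#' @export
final_score <- function(usability, confidentiality_pct,
                        confidentiality_value = NULL, labels = NULL) {
  if (is.null(confidentiality_value)) {
    confidentiality_value <- confidentiality_value(confidentiality_pct)
  }
  structure(
    list(usability = as.integer(usability),
         confidentiality_pct = confidentiality_pct,
         confidentiality_value = as.integer(confidentiality_value),
         final_score = as.integer(usability + confidentiality_value),
         labels = labels),
    class = "deid_score"
  )
}

#' @export
print.deid_score <- function(x, ...) {
  cat(sprintf(
    "usability %d | confidentiality %.2f%% (band score %d) | final score %d\n",
    x$usability, x$confidentiality_pct, x$confidentiality_value,
    x$final_score))
  invisible(x)
}
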