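#' Define a per-field masking policy
#'
#' A masking policy specifies, for each of the seven record fields, how
#' many characters are replaced by `*`. One policy corresponds to one
#' de-identification methodology.
#'
#' @param name_level Number of the 3 name tokens masked (0--3).
#' @param age_level Number of the 2 age digits masked (0--2).
#' @param phone_level `"none"` (no masking), `"partial"` (7 of the 8
#'   random digits masked, pattern `010-d***-****`) or `"full"`
#'   (`***-****-****`).
#' @param blood_mask,region_mask,illness_mask,smoking_mask Logical; `TRUE`
#'   replaces the whole categorical value by `*`.
#' @return An object of class `deid_policy`.
#' @export
#' @examples
#' masking_policy(name_level = 1, age_level = 1, phone_level = "partial",
#'                illness_mask = TRUE)
masking_policy <- function(name_level = 0L, age_level = 0L,
                           phone_level = c("none", "partial", "full"),
                           blood_mask = FALSE, region_mask = FALSE,
                           illness_mask = FALSE, smoking_mask = FALSE) {
  phone_level <- match.arg(phone_level)
  name_level <- as.integer(name_level)
  age_level <- as.integer(age_level)
  if (is.na(name_level) || name_level < 0L || name_level > 3L) {
    stop("name_level must be in 0:3", call. = FALSE)
  }
  if (is.na(age_level) || age_level < 0L || age_level > 2L) {
    stop("age_level must be in 0:2", call. = FALSE)
  }
  for (flag in list(blood_mask, region_mask, illness_mask, smoking_mask)) {
    if (!is.logical(flag) || length(flag) != 1L || is.na(flag)) {
      stop("categorical mask flags must be TRUE or FALSE", call. = FALSE)
    }
  }
  structure(
    list(name_level = name_level, age_level = age_level,
         phone_level = phone_level, blood_mask = blood_mask,
         region_mask = region_mask, illness_mask = illness_mask,
         smoking_mask = smoking_mask),
    class = "deid_policy"
  )
}

#' @export
print.deid_policy <- function(x, ...) {
  cat(sprintf(
    "Masking policy: name %d/3, age %d/2, phone %s; masked categoricals: %s\n",
    x$name_level, x$age_level, x$phone_level,
    {
      flags <- c(blood = x$blood_mask, region = x$region_mask,
                 illness = x$illness_mask, smoking = x$smoking_mask)
      if (any(flags)) paste(names(flags)[flags], collapse = ", ") else "none"
    }))
  invisible(x)
}

#' Mask name tokens
#'
#' Names are three space-separated tokens (family + two given-name
#' tokens). `level` tokens are replaced by `*`, in the fixed order: first
#' given token, second given token, family token. The label code does not
#' depend on which token is masked, but a deterministic order is needed so
#' that deduplication is reproducible.
#'
#' @param name Character vector of 3-token names.
#' @param level Integer in 0--3: number of tokens masked.
#' @return Character vector of masked names.
#' @export
#' @examples
#' mask_name("Lee Jun Hak", 1)  # "Lee * Hak"
mask_name <- function(name, level) {
  level <- as.integer(level)
  if (length(level) != 1L || is.na(level) || level < 0L || level > 3L) {
    stop("name masking level must be in 0:3", call. = FALSE)
  }
  if (level == 0L) return(name)
  toks <- strsplit(name, " ", fixed = TRUE)
  # token positions in masking order: given1 (2), given2 (3), family (1)
  masked_pos <- c(2L, 3L, 1L)[seq_len(level)]
  vapply(toks, function(tk) {
    if (length(tk) != 3L) stop("name must have 3 tokens", call. = FALSE)
    tk[masked_pos] <- "*"
    paste(tk, collapse = " ")
  }, character(1))
}

#' Mask the two-digit age rendering
#'
#' Ages are rendered on two digits within their century (25 -> "25",
#' 7 -> "07", 103 -> "03"); level 1 masks the ones digit, level 2 both.
#'
#' @param age Integer vector of ages in `[0, 109]`.
#' @param level Integer in 0--2: number of digits masked.
#' @return Character vector of masked two-character age strings.
#' @export
#' @examples
#' mask_age(12, 1)  # "1*"
mask_age <- function(age, level) {
  level <- as.integer(level)
  if (length(level) != 1L || is.na(level) || level < 0L || level > 2L) {
    stop("age masking level must be in 0:2", call. = FALSE)
  }
  if (any(is.na(age)) || any(age < 0) || any(age > 109)) {
    stop("ages must lie in [0, 109]", call. = FALSE)
  }
  s <- sprintf("%02d", as.integer(age) %% 100L)
  if (level == 1L) s <- paste0(substr(s, 1L, 1L), "*")
  if (level == 2L) s <- rep("**", length(s))
  s
}

#' Mask a phone number
#'
#' `"partial"` keeps the `010-` prefix and the first random digit and
#' masks the remaining seven (`010-7123-4567` -> `010-7***-****`);
#' `"full"` masks every character including the prefix
#' (`***-****-****`).
#'
#' @param phone Character vector matching `010-dddd-dddd`.
#' @param level One of `"none"`, `"partial"`, `"full"`.
#' @return Character vector of masked phone strings.
#' @export
mask_phone <- function(phone, level = c("none", "partial", "full")) {
  level <- match.arg(level)
  ok <- grepl("^010-[0-9]{4}-[0-9]{4}$", phone)
  if (!all(ok)) {
    stop("malformed phone number: ", phone[!ok][1], call. = FALSE)
  }
  switch(level,
         none = phone,
         partial = paste0(substr(phone, 1L, 5L), "***-****"),
         full = rep("***-****-****", length(phone)))
}

#' Mask a categorical value
#'
#' Categorical fields (blood type, region, illness, smoking status) are
#' either kept verbatim or replaced entirely by a single `*`: partially
#' masking a label from a small closed set would not prevent grouping.
#'
#' @param value Character vector of labels.
#' @param masked Logical scalar.
#' @return `value` unchanged, or `"*"` for every element.
#' @export
mask_categorical <- function(value, masked) {
  if (!is.logical(masked) || length(masked) != 1L || is.na(masked)) {
    stop("masked must be TRUE or FALSE", call. = FALSE)
  }
  if (masked) rep("*", length(value)) else as.character(value)
}

# Canonical string rendering of an unmasked cohort: the representation
# masking operates on (ages on two digits, smoking as O/X).
render_cohort <- function(cohort) {
  data.frame(
    name = cohort$name,
    age = sprintf("%02d", cohort$age %% 100L),
    phone = cohort$phone,
    region = cohort$region,
    illness = cohort$illness,
    blood = cohort$blood,
    smoking = ifelse(cohort$smoking, "O", "X"),
    stringsAsFactors = FALSE
  )
}

#' Apply a masking policy to a cohort
#'
#' Element-wise, order-preserving application of the four masking
#' operations to every record. Smoking status is rendered `O`/`X` before
#' masking; ages are rendered on two digits.
#'
#' @param cohort A cohort data.frame from [generate_cohort()].
#' @param policy A `deid_policy`.
#' @return A data.frame of masked string fields with the same column
#'   names and row order as the cohort.
#' @export
#' @examples
#' cohort <- generate_cohort(3, seed = 7)
#' apply_policy(cohort, masking_policy(name_level = 3, phone_level = "full"))
apply_policy <- function(cohort, policy) {
  stopifnot(inherits(policy, "deid_policy"))
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  data.frame(
    name = mask_name(cohort$name, policy$name_level),
    age = mask_age(cohort$age, policy$age_level),
    phone = mask_phone(cohort$phone, policy$phone_level),
    region = mask_categorical(cohort$region, policy$region_mask),
    illness = mask_categorical(cohort$illness, policy$illness_mask),
    blood = mask_categorical(cohort$blood, policy$blood_mask),
    smoking = mask_categorical(ifelse(cohort$smoking, "O", "X"),
                               policy$smoking_mask),
    stringsAsFactors = FALSE
  )
}
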