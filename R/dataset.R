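#' Enumerate the full masking-policy space
#'
#' The Cartesian product of all per-field masking levels: 4 name levels
#' x 3 age levels x 3 phone levels x 2^4 categorical flags = 576
#' policies, in a fixed canonical order starting with the all-unmasked
#' policy (the smoking flag varies fastest, the name level slowest).
#'
#' @return A list of 576 `deid_policy` objects.
#' @export
enumerate_policies <- function() {
  grid <- expand.grid(
    smoking_mask = c(FALSE, TRUE),
    illness_mask = c(FALSE, TRUE),
    region_mask = c(FALSE, TRUE),
    blood_mask = c(FALSE, TRUE),
    phone_level = c("none", "partial", "full"),
    age_level = 0:2,
    name_level = 0:3,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    masking_policy(name_level = g$name_level, age_level = g$age_level,
                   phone_level = g$phone_level, blood_mask = g$blood_mask,
                   region_mask = g$region_mask, illness_mask = g$illness_mask,
                   smoking_mask = g$smoking_mask)
  })
}

# Score every policy against one cohort. Masked renderings of each field
# depend only on that field's level, so each variant column is computed
# once with the masking operations and policies only recombine columns.
score_policies_on_cohort <- function(cohort, policies) {
  n <- nrow(cohort)
  cols <- list(
    name = lapply(0:3, function(l) mask_name(cohort$name, l)),
    age = lapply(0:2, function(l) mask_age(cohort$age, l)),
    phone = lapply(c("none", "partial", "full"),
                   function(l) mask_phone(cohort$phone, l)),
    blood = lapply(c(FALSE, TRUE),
                   function(m) mask_categorical(cohort$blood, m)),
    region = lapply(c(FALSE, TRUE),
                    function(m) mask_categorical(cohort$region, m)),
    illness = lapply(c(FALSE, TRUE),
                     function(m) mask_categorical(cohort$illness, m)),
    smoking = lapply(c(FALSE, TRUE), function(m)
      mask_categorical(ifelse(cohort$smoking, "O", "X"), m))
  )
  vapply(policies, function(p) {
    key <- paste(
      cols$name[[p$name_level + 1L]],
      cols$age[[p$age_level + 1L]],
      cols$phone[[match(p$phone_level, c("none", "partial", "full"))]],
      cols$blood[[p$blood_mask + 1L]],
      cols$region[[p$region_mask + 1L]],
      cols$illness[[p$illness_mask + 1L]],
      cols$smoking[[p$smoking_mask + 1L]],
      sep = "\r")
    labels <- label_policy(p)
    pct <- length(unique(key)) / n * 100
    c(usability(labels) + confidentiality_value(pct))
  }, numeric(1))
}

#' Build the de-identification regression dataset
#'
#' For each cohort size (and replicate), generates a synthetic cohort
#' with a seed derived deterministically from `seed`, applies every
#' policy of [enumerate_policies()], and records one row per (cohort,
#' policy) pair: the cohort size, the seven label codes (the independent
#' variables) and the final score (the dependent variable).
#'
#' @param sizes Integer vector of cohort sizes. The default
#'   `c(100, 500, 1000, 5000)` spans the confidentiality bands while
#'   staying desk-scale.
#' @param replicates Cohorts generated per size (default 1).
#' @param seed Master integer seed.
#' @param spec A `deid_demographics` object.
#' @return A data.frame with columns `n_samples`, `name`, `age`,
#'   `phone`, `blood`, `region`, `illness`, `smoking`, `final_score`
#'   and `|sizes| * replicates * 576` rows.
#' @export
#' @examples
#' \donttest{
#' ds <- build_dataset(sizes = 100, seed = 1)
#' nrow(ds)  # 576
#' }
build_dataset <- function(sizes = c(100L, 500L, 1000L, 5000L),
                          replicates = 1L, seed = 42L,
                          spec = default_demographics()) {
  if (length(sizes) == 0L || anyNA(sizes) || any(sizes < 1)) {
    stop("sizes must be positive integers", call. = FALSE)
  }
  if (length(replicates) != 1L || is.na(replicates) || replicates < 1) {
    stop("replicates must be >= 1", call. = FALSE)
  }
  policies <- enumerate_policies()
  labels <- t(vapply(policies, label_policy, integer(7)))
  colnames(labels) <- c("name", "age", "phone", "blood", "region",
                        "illness", "smoking")
  out <- vector("list", length(sizes) * replicates)
  k <- 0L
  for (i in seq_along(sizes)) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      cohort <- generate_cohort(sizes[i], spec,
                                seed = derive_seed(seed, k))
      scores <- score_policies_on_cohort(cohort, policies)
      out[[k]] <- data.frame(n_samples = as.integer(sizes[i]), labels,
                             final_score = as.integer(scores))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read and write the regression dataset CSV
#'
#' @param dataset A data.frame from [build_dataset()].
#' @param path File path.
#' @return `read_dataset()` returns the dataset data.frame;
#'   `write_dataset()` returns `path` invisibly.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c("n_samples", "name", "age", "phone", "blood", "region",
                "illness", "smoking", "final_score")
  if (!identical(names(df), expected)) {
    stop("dataset CSV must have header ", paste(expected, collapse = ","),
         call. = FALSE)
  }
  df
}
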