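#' Load demographic probability tables
#'
#' Reads the demographic specification used by the synthetic cohort
#' generator: family-name shares, decade age bands, residential areas,
#' blood types, the smoking rate and the illness label set. Probability
#' vectors are validated and renormalized to sum to exactly 1 (several of
#' the published percentage vectors sum to e.g. 99.5 or 100.2 because the
#' sources round each entry independently); the printed percentages are
#' retained in the `printed` element for reporting.
#'
#' @param path Path to a YAML demographics file. Defaults to the tables
#'   bundled with the package.
#' @return An object of class `deid_demographics` with elements
#'   `family_names`, `age_bands`, `regions`, `blood_types` (each a
#'   data.frame with a normalized `prob` column), `smoking_prob`,
#'   `illnesses`, and `printed` (the raw percentage vectors as published).
#' @export
#' @examples
#' spec <- default_demographics()
#' sum(spec$blood_types$prob)  # exactly 1 after renormalization
load_demographics <- function(path) {
  if (!file.exists(path)) {
    stop("demographics file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  need <- c("family_names", "age_bands", "regions", "blood_types",
            "smoking_percent", "illnesses")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("demographics configuration is missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  cat_table <- function(block, name, n_expected) {
    labels <- as.character(block$labels)
    pct <- as.numeric(block$percent)
    if (length(labels) != length(pct)) {
      stop("demographics '", name, "': labels and percent differ in length",
           call. = FALSE)
    }
    if (length(labels) != n_expected) {
      stop("demographics '", name, "': expected ", n_expected,
           " categories, got ", length(labels), call. = FALSE)
    }
    if (anyNA(pct) || any(pct < 0)) {
      stop("demographics '", name, "': probabilities must be non-negative",
           call. = FALSE)
    }
    if (sum(pct) <= 0) {
      stop("demographics '", name, "': probabilities sum to zero", call. = FALSE)
    }
    data.frame(label = labels, prob = pct / sum(pct),
               stringsAsFactors = FALSE)
  }

  fam <- cat_table(raw$family_names, "family_names", 21L)
  reg <- cat_table(raw$regions, "regions", 17L)
  blood <- cat_table(raw$blood_types, "blood_types", 4L)
  if (!identical(sort(blood$label), sort(c("A", "B", "O", "AB")))) {
    stop("demographics 'blood_types': labels must be A, B, O, AB", call. = FALSE)
  }

  ab <- raw$age_bands
  age_pct <- as.numeric(ab$percent)
  if (length(ab$lower) != 11L || length(ab$upper) != 11L ||
      length(age_pct) != 11L) {
    stop("demographics 'age_bands': expected 11 decade bands", call. = FALSE)
  }
  if (anyNA(age_pct) || any(age_pct < 0)) {
    stop("demographics 'age_bands': probabilities must be non-negative",
         call. = FALSE)
  }
  age <- data.frame(lower = as.integer(ab$lower), upper = as.integer(ab$upper),
                    prob = age_pct / sum(age_pct))
  if (any(age$lower > age$upper)) {
    stop("demographics 'age_bands': lower bound above upper bound", call. = FALSE)
  }

  smoking_pct <- as.numeric(raw$smoking_percent)
  if (is.na(smoking_pct) || smoking_pct < 0 || smoking_pct > 100) {
    stop("demographics 'smoking_percent' must lie in [0, 100]", call. = FALSE)
  }

  illnesses <- as.character(raw$illnesses)
  if (length(illnesses) != 5L) {
    stop("demographics 'illnesses': expected 5 labels", call. = FALSE)
  }

  structure(
    list(
      family_names = fam,
      age_bands = age,
      regions = reg,
      blood_types = blood,
      smoking_prob = smoking_pct / 100,
      illnesses = illnesses,
      printed = list(
        family_names = as.numeric(raw$family_names$percent),
        age_bands = age_pct,
        regions = as.numeric(raw$regions$percent),
        blood_types = as.numeric(raw$blood_types$percent),
        smoking = smoking_pct
      )
    ),
    class = "deid_demographics"
  )
}

#' @rdname load_demographics
#' @export
default_demographics <- function() {
  load_demographics(system.file("extdata", "demographics.yaml",
                                package = "deidverify", mustWork = TRUE))
}

#' @export
print.deid_demographics <- function(x, ...) {
  cat("Demographic specification:\n")
  cat("  family names :", nrow(x$family_names), "categories (",
      x$family_names$label[1], "=",
      sprintf("%.2f%%", 100 * x$family_names$prob[1]), ")\n")
  cat("  age bands    :", nrow(x$age_bands), "decade bands, 0 -",
      max(x$age_bands$upper), "\n")
  cat("  regions      :", nrow(x$regions), "areas\n")
  cat("  blood types  :", paste(x$blood_types$label, collapse = "/"), "\n")
  cat("  smoking rate :", sprintf("%.1f%%", 100 * x$smoking_prob), "\n")
  cat("  illnesses    :", paste(x$illnesses, collapse = ", "), "\n")
  invisible(x)
}

# Fixed alphabet of 100 synthetic given-name syllable tokens. The sources
# publish no given-name distribution, so given names are opaque uniform
# tokens; only their count (two per person) matters to the masking rules.
given_name_syllables <- function() {
  onsets <- c("Ka", "Na", "Da", "Ra", "Ma", "Ba", "Sa", "Ja", "Cha", "Ha",
              "Ga", "Ta", "Pa", "Ya", "Wa", "La", "Min", "Seo", "Hyun", "Eun")
  as.vector(outer(onsets, c("n", "m", "k", "e", "o"), paste0))
}

# Run `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so cohort generation never disturbs an analysis stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic derived seed for stream k of a master seed; kept below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 100000) * 20011 + 7919 * as.numeric(k)) %%
    2147483646L + 1L
}

#' Sample category indices from a discrete distribution
#'
#' Shared seeded sampler behind the name, region, blood-type and illness
#' fields. Draws from the current RNG stream; wrap in [generate_cohort()]
#' or `set.seed()` for reproducibility.
#'
#' @param n Number of draws.
#' @param weights Non-negative weight vector (normalized internally).
#' @return Integer vector of category indices in `1:length(weights)`.
#' @export
sample_categorical <- function(n, weights) {
  if (length(weights) == 0L) stop("empty weight vector", call. = FALSE)
  if (anyNA(weights) || any(weights < 0)) {
    stop("weights must be non-negative", call. = FALSE)
  }
  sample.int(length(weights), size = n, replace = TRUE, prob = weights)
}

#' Sample integer ages from the decade-band distribution
#'
#' A band is drawn from the 11 decade-band probabilities, then the age is
#' uniform over the band's integer range. The open-ended "100 and over"
#' band is realized as uniform on 100--109.
#'
#' @param n Number of draws.
#' @param spec A `deid_demographics` object.
#' @return Integer vector of ages in `[0, 109]`.
#' @export
sample_age <- function(n, spec) {
  bands <- spec$age_bands
  idx <- sample_categorical(n, bands$prob)
  lo <- bands$lower[idx]
  hi <- bands$upper[idx]
  lo + floor(stats::runif(n) * (hi - lo + 1L))
}

#' Sample unique mobile phone numbers
#'
#' Phone numbers follow the Korean mobile convention: the common "010"
#' prefix followed by eight uniformly random digits. Uniqueness within a
#' cohort (and against `used`) is enforced by rejection sampling, mirroring
#' real numbering where no two subscribers share a number.
#'
#' @param n Number of phones to draw.
#' @param used Character vector of phone strings already taken.
#' @return Character vector of `n` distinct strings matching
#'   `010-dddd-dddd`, none of which appear in `used`.
#' @export
sample_phone <- function(n, used = character()) {
  if (n + length(used) >= 1e8) {
    stop("phone number space exhausted", call. = FALSE)
  }
  draw <- function(m) {
    a <- sample.int(10000L, m, replace = TRUE) - 1L
    b <- sample.int(10000L, m, replace = TRUE) - 1L
    sprintf("010-%04d-%04d", a, b)
  }
  phones <- draw(n)
  repeat {
    bad <- duplicated(phones) | phones %in% used
    if (!any(bad)) break
    phones[bad] <- draw(sum(bad))
  }
  phones
}

#' Generate a synthetic medical cohort
#'
#' Draws `n` independent person records whose fields follow the configured
#' demographic distributions: a 3-token name (family name from the 21-way
#' published distribution, two uniform synthetic given-name syllables), a
#' decade-banded age, a unique `010-dddd-dddd` phone number, one of 17
#' residential areas, one of 5 uniformly distributed illnesses, an ABO
#' blood type, and a Bernoulli smoking flag. Fields are sampled
#' independently of one another.
#'
#' @param n Cohort size (positive integer).
#' @param spec A `deid_demographics` object; defaults to the bundled tables.
#' @param seed Integer seed; the same `(n, spec, seed)` always yields an
#'   identical cohort and the caller's RNG state is left untouched.
#' @return A data.frame with columns `name` (three space-separated
#'   tokens), `age` (integer), `phone`, `region`, `illness`, `blood`
#'   (character) and `smoking` (logical).
#' @export
#' @examples
#' cohort <- generate_cohort(5, seed = 1)
#' cohort$name
generate_cohort <- function(n, spec = default_demographics(), seed = 42L) {
  if (length(n) != 1L || is.na(n) || n < 1) {
    stop("cohort size n must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  stopifnot(inherits(spec, "deid_demographics"))
  with_seed(seed, {
    fam <- spec$family_names$label[sample_categorical(n, spec$family_names$prob)]
    syll <- given_name_syllables()
    g1 <- syll[sample.int(length(syll), n, replace = TRUE)]
    g2 <- syll[sample.int(length(syll), n, replace = TRUE)]
    data.frame(
      name = paste(fam, g1, g2),
      age = as.integer(sample_age(n, spec)),
      phone = sample_phone(n),
      region = spec$regions$label[sample_categorical(n, spec$regions$prob)],
      illness = spec$illnesses[sample.int(5L, n, replace = TRUE)],
      blood = spec$blood_types$label[sample_categorical(n, spec$blood_types$prob)],
      smoking = stats::runif(n) < spec$smoking_prob,
      stringsAsFactors = FALSE
    )
  })
}

#' Read and write cohort CSV files
#'
#' Cohorts are persisted as plain CSV with the header
#' `name,age,phone,region,illness,blood,smoking`.
#'
#' @param cohort A cohort data.frame as returned by [generate_cohort()].
#' @param path File path.
#' @return `read_cohort()` returns the cohort data.frame;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(age = "integer", smoking = "logical"))
  expected <- c("name", "age", "phone", "region", "illness", "blood", "smoking")
  if (!identical(names(df), expected)) {
    stop("cohort CSV must have header ", paste(expected, collapse = ","),
         call. = FALSE)
  }
  df
}
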