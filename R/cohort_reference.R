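# Default 83-center study profile and the printed-count split reconstruction.
#
# The default synthetic cohort emulates the structure of the largest published
# multi-center Parkinson's disease MRI collection: 83 centers contributed by 14
# studies — one 42-center study, one 24-center study, one 6-center study and 11
# single-center studies — with a long-tailed size distribution (several centers
# holding fewer than 5 scans), study-specific disease and sex mixes (some
# studies are healthy-only or disease-only), and vendor structure. The raw
# per-study scan counts sum to 2,091 but the usable cohort holds 1,817 scans;
# the default profile rescales study totals so the generated cohort totals
# exactly 1,817.

.STUDY_TABLE <- data.frame(
  study = c("ADNI", "BIOCOG", "CBIG", "HAMBURG", "CCNA", "JAPAN", "NEUROCON",
            "OASIS", "PDMCICAL", "PDMCIPLS", "PPMI", "SALD", "TAOWU", "UKBB"),
  n_centers = c(42L, 1L, 1L, 1L, 6L, 1L, 1L, 1L, 1L, 1L, 24L, 1L, 1L, 1L),
  n_scans = c(564L, 94L, 76L, 113L, 57L, 45L, 42L, 27L, 121L, 62L, 530L, 78L,
              37L, 245L),
  disease_fraction = c(0, 45 / 94, 66 / 76, 74 / 113, 1, 30 / 45, 26 / 42, 0,
                       79 / 121, 41 / 62, 364 / 530, 0, 17 / 37, 48 / 245),
  male_fraction = c(96 / 273, 53 / 94, 37 / 76, 76 / 113, 37 / 57, 20 / 45,
                    20 / 42, 17 / 27, 73 / 121, 36 / 62, 336 / 530, 1,
                    20 / 37, 147 / 245),
  mixed_vendors = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                    FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
  ge_only = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE,
              FALSE, FALSE, FALSE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

.COHORT_TOTAL <- 1817L

# Printed split counts: rows disease/healthy, columns are train/test by sex.
.SPLIT_COUNTS <- data.frame(
  label = c(1L, 0L),
  male_train = c(418L, 400L), male_test = c(124L, 120L),
  female_train = c(262L, 330L), female_test = c(63L, 100L)
)

#' Study-level structure of the default multi-center profile
#'
#' One row per contributing study: number of centers, raw scan count,
#' disease and male fractions, and vendor structure. The `n_centers` column
#' sums to 83.
#'
#' @return data.frame with columns `study`, `n_centers`, `n_scans`,
#'   `disease_fraction`, `male_fraction`, `mixed_vendors`, `ge_only`.
#' @export
study_table <- function() .STUDY_TABLE

# Largest-remainder apportionment of `total` units over positive weights,
# with every part at least 1.
apportion <- function(total, weights) {
  k <- length(weights)
  stopifnot(total >= k, all(weights > 0))
  q <- total * weights / sum(weights)
  s <- floor(q)
  extra <- total - sum(s)
  if (extra > 0) {
    ord <- order(q - s, decreasing = TRUE)
    s[ord[seq_len(extra)]] <- s[ord[seq_len(extra)]] + 1
  }
  while (any(s == 0)) {
    i <- which(s == 0)[1]
    j <- which.max(s)
    s[i] <- 1
    s[j] <- s[j] - 1
  }
  as.integer(s)
}

#' Default 83-center cohort specification
#'
#' Builds a [cohort_spec()] reproducing the structure of the reference
#' multi-center collection: 83 centers from 14 studies with a long-tailed
#' size distribution. Within multi-center studies, per-center sizes are drawn
#' by apportioning the study total over skewed Gamma(0.6) weights (largest
#' remainder, minimum 1), so some centers end up with fewer than 5
#' participants. Study totals are rescaled (largest remainder) so the cohort
#' totals `round(1817 * scale)`.
#'
#' @param master_seed seed for [build_cohort()] determinism.
#' @param scale overall size multiplier; `scale = 1` gives 1,817 records,
#'   smaller values keep the 83-center structure with proportionally fewer
#'   participants per center (total never below 83, one per center).
#' @return a `cohort_spec` with 83 declared centers.
#' @export
reference_cohort_spec <- function(master_seed = 42L, scale = 1) {
  st <- .STUDY_TABLE
  target <- max(round(.COHORT_TOTAL * scale), sum(st$n_centers))
  totals <- apportion(target, st$n_scans)
  # every study must be able to give each center >= 1 participant
  short <- which(totals < st$n_centers)
  for (i in short) totals[i] <- st$n_centers[i]
  if (sum(totals) > target) {
    excess <- sum(totals) - target
    room <- totals - st$n_centers
    j <- which.max(room)
    totals[j] <- totals[j] - min(excess, room[j])
  }

  groups <- lapply(seq_len(nrow(st)), function(i) {
    tot <- totals[i]
    nc <- st$n_centers[i]
    vw <- if (st$mixed_vendors[i]) {
      c(Siemens = 0.5, GE = 0.3, Philips = 0.2)
    } else if (st$ge_only[i]) {
      c(Siemens = 0, GE = 1, Philips = 0)
    } else {
      c(Siemens = 1, GE = 0, Philips = 0)
    }
    list(
      name = st$study[i],
      n_centers = nc,
      size_sampler = if (nc == 1L) {
        function(n) tot
      } else {
        function(n) apportion(tot, stats::rgamma(n, shape = 0.6, rate = 1) + 1e-9)
      },
      label_fraction_sampler = local({
        f <- st$disease_fraction[i]
        function(n) rep(f, n)
      }),
      sex_fraction_sampler = local({
        f <- st$male_fraction[i]
        function(n) rep(f, n)
      }),
      vendor_weights = vw
    )
  })
  cohort_spec(center_size_profile = groups, master_seed = master_seed)
}

#' Reconstruct the reference split from printed counts
#'
#' Rebuilds a train/test cohort whose marginal counts match the published
#' split table of the reference collection exactly: 680/187 disease-positive
#' and 730/220 healthy train/test records with the stated male/female
#' breakdown — 1,410 train and 407 test records, 1,817 in total. Ages,
#' centers and scanner fields are synthetic filler (the printed table fixes
#' only label, sex and split); the arithmetic of the totals is what this
#' object carries.
#'
#' @param master_seed seed for the filler demographics.
#' @return a `split_cohort`.
#' @export
reference_split_cohort <- function(master_seed = 42L) {
  rows <- list()
  with_seed(master_seed, {
    k <- 0L
    for (i in seq_len(nrow(.SPLIT_COUNTS))) {
      cnt <- .SPLIT_COUNTS[i, ]
      for (grp in list(c("M", "train", cnt$male_train), c("M", "test", cnt$male_test),
                       c("F", "train", cnt$female_train), c("F", "test", cnt$female_test))) {
        n <- as.integer(grp[3])
        if (n == 0L) next
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = sprintf("ref_p%04d", k + seq_len(n)),
          center_id = "reference_c01",
          label = cnt$label, sex = grp[1],
          age_years = round(pmin(pmax(stats::rnorm(n, 64, 9), 35), 90), 1),
          vendor = "Siemens", field_strength_tesla = 3.0, split = grp[2],
          stringsAsFactors = FALSE
        )
        k <- k + n
      }
    }
  })
  make_split_cohort(as_cohort(do.call(rbind, rows)))
}
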