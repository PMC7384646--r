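#' Racial residential segregation score (RRS)
#'
#' Concentration-at-the-extremes score for the non-Hispanic white and
#' non-Hispanic black populations of a census block group:
#' \deqn{RRS = (n_{white} - n_{black}) / n_{total}.}
#' The score lies in \[-1, 1\]: values near -1 indicate a high black-to-white
#' resident ratio, values near 1 a low one, and 0 an equal number of
#' non-Hispanic white and black residents.
#'
#' @param n_white Count of non-Hispanic white residents (vectorized).
#' @param n_black Count of non-Hispanic black residents.
#' @param n_total Total population of the block group; must be positive.
#' @return Numeric vector of scores in \[-1, 1\].
#' @examples
#' compute_rrs(900, 100, 1000)   # 0.8, a predominantly white block group
#' compute_rrs(0, 450, 450)      # -1, an entirely black block group
#' @export
compute_rrs <- function(n_white, n_black, n_total) {
  stopifnot(length(n_white) == length(n_black),
            length(n_black) == length(n_total))
  if (any(!is.finite(n_white)) || any(!is.finite(n_black)) ||
      any(!is.finite(n_total))) {
    stop("race counts must be finite")
  }
  if (any(n_white < 0) || any(n_black < 0)) {
    stop("race counts must be non-negative")
  }
  if (any(n_total < n_white + n_black)) {
    stop("n_total must be at least n_white + n_black")
  }
  if (any(n_total <= 0)) {
    stop("RRS is undefined for block groups with zero total population; ",
         "flag and exclude these units")
  }
  (n_white - n_black) / n_total
}

#' Tract-level index of racial dissimilarity (IRD)
#'
#' Classical index of dissimilarity comparing the distribution of
#' non-Hispanic black and white residents across the block groups of one
#' census tract:
#' \deqn{D = 50 \sum_i | b_i / B - w_i / W |}
#' where \eqn{b_i}, \eqn{w_i} are block-group counts and \eqn{B}, \eqn{W}
#' the tract totals. D is a percentage in \[0, 100\]: 0 when every block
#' group has the same racial mix as the tract, 100 under complete
#' separation. The tract-level value is assigned to every member block
#' group.
#'
#' @param n_black,n_white Block-group counts within a single tract.
#' @param block_group_id Optional ids used to name the result.
#' @return Named numeric vector (one identical value per block group).
#' @examples
#' compute_ird(n_black = c(100, 0), n_white = c(0, 100))  # 100, 100
#' compute_ird(n_black = c(30, 10), n_white = c(70, 90))  # 31.25, 31.25
#' @export
compute_ird <- function(n_black, n_white, block_group_id = NULL) {
  stopifnot(length(n_black) == length(n_white))
  if (any(n_black < 0) || any(n_white < 0)) {
    stop("race counts must be non-negative")
  }
  B <- sum(n_black)
  W <- sum(n_white)
  if (B <= 0 || W <= 0) {
    stop("IRD is undefined for tracts with no black or no white residents; ",
         "flag and exclude this tract")
  }
  d <- 50 * sum(abs(n_black / B - n_white / W))
  out <- rep(d, length(n_black))
  if (!is.null(block_group_id)) names(out) <- as.character(block_group_id)
  out
}

#' Categorize RRS into five segregation groups
#'
#' Bins an RRS score into five ordered categories. The first two groups
#' indicate predominantly black block groups, the middle group a roughly
#' equal distribution, and the last two predominantly white block groups.
#' The bin edges are -1, -0.5, -0.1, 0.1, 0.5, 1, with half-open
#' assignment so that every value of \[-1, 1\] falls in exactly one bin:
#' G1 = \[-1, -0.5), G2 = \[-0.5, -0.1), G3 = \[-0.1, 0.1\],
#' G4 = (0.1, 0.5\], G5 = (0.5, 1\]. G1 (most black-segregated) is the
#' reference level in downstream interaction models.
#'
#' @param rrs Numeric vector of scores in \[-1, 1\].
#' @return Factor with levels `G1` ... `G5`.
#' @export
categorize_rrs <- function(rrs) {
  if (any(!is.finite(rrs)) || any(rrs < -1) || any(rrs > 1)) {
    stop("rrs must lie in [-1, 1]")
  }
  idx <- ifelse(rrs < -0.5, 1L,
         ifelse(rrs < -0.1, 2L,
         ifelse(rrs <= 0.1, 3L,
         ifelse(rrs <= 0.5, 4L, 5L))))
  factor(paste0("G", idx), levels = paste0("G", 1:5))
}

#' Read and validate a census race-count table
#'
#' Expects a CSV with header
#' `block_group_id,tract_id,n_white,n_black,n_total`. Validates count
#' invariants and block-group/tract nesting.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` of validated census units.
#' @export
read_census_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    block_group_id = "character", tract_id = "character"))
  validate_census(df)
}

#' Validate a census race-count table
#'
#' @param df Data frame with columns `block_group_id`, `tract_id`,
#'   `n_white`, `n_black`, `n_total`.
#' @return The validated data frame, invisibly unchanged.
#' @export
validate_census <- function(df) {
  need <- c("block_group_id", "tract_id", "n_white", "n_black", "n_total")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("census table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$block_group_id)) {
    stop("duplicate block_group_id in census table")
  }
  if (any(df$n_white < 0) || any(df$n_black < 0) || any(df$n_total < 0)) {
    stop("negative counts in census table")
  }
  if (any(df$n_total < df$n_white + df$n_black)) {
    stop("n_total smaller than n_white + n_black for some block groups")
  }
  df
}

#' Block-group racial composition and segregation scores
#'
#' Computes, for every block group in a census race-count table, percent
#' non-Hispanic white and black residents (denominator: total population),
#' the RRS concentration score, its five-level category, and the
#' tract-level index of racial dissimilarity.
#'
#' Block groups with zero total population get `NA` scores and are listed
#' in the `excluded` attribute; tracts with no black or no white
#' residents get `NA` IRD and are listed in the `ird_undefined`
#' attribute. Downstream analyses drop these rather than treating the
#' scores as zero.
#'
#' @param census Census table as returned by [read_census_csv()].
#' @return Data frame with columns `block_group_id`, `pct_white`,
#'   `pct_black`, `rrs`, `rrs_category`, `ird`, plus attributes
#'   `excluded` (zero-population block groups) and `ird_undefined`
#'   (tracts with an undefined dissimilarity index).
#' @export
segregation_scores <- function(census) {
  census <- validate_census(census)
  ok <- census$n_total > 0
  pct_white <- pct_black <- rrs <- rep(NA_real_, nrow(census))
  pct_white[ok] <- 100 * census$n_white[ok] / census$n_total[ok]
  pct_black[ok] <- 100 * census$n_black[ok] / census$n_total[ok]
  rrs[ok] <- compute_rrs(census$n_white[ok], census$n_black[ok],
                         census$n_total[ok])
  rrs_category <- factor(rep(NA_character_, nrow(census)),
                         levels = paste0("G", 1:5))
  rrs_category[ok] <- categorize_rrs(rrs[ok])

  ird <- rep(NA_real_, nrow(census))
  ird_undefined <- character(0)
  for (tr in unique(census$tract_id)) {
    sel <- census$tract_id == tr
    B <- sum(census$n_black[sel])
    W <- sum(census$n_white[sel])
    if (B <= 0 || W <= 0) {
      ird_undefined <- c(ird_undefined, tr)
    } else {
      ird[sel] <- compute_ird(census$n_black[sel], census$n_white[sel])
    }
  }

  out <- data.frame(
    block_group_id = census$block_group_id,
    pct_white = pct_white, pct_black = pct_black,
    rrs = rrs, rrs_category = rrs_category, ird = ird,
    stringsAsFactors = FALSE)
  attr(out, "excluded") <- census$block_group_id[!ok]
  attr(out, "ird_undefined") <- ird_undefined
  out
}

#' Write a segregation-scores table to CSV
#'
#' @param scores Result of [segregation_scores()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
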