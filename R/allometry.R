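#' Build a tree record table
#'
#' @param species_code character vector of species codes.
#' @param dbh diameter at breast height, cm (> 0).
#' @param height total height, m, or `NA` when not measured. A present height
#'   must exceed breast height (1.37 m).
#' @param height_is_measured logical; defaults to `!is.na(height)`.
#' @return data.frame of validated tree records.
#' @export
tree_records <- function(species_code, dbh, height = NA_real_,
                         height_is_measured = !is.na(height)) {
  n <- length(dbh)
  height <- rep_len(as.numeric(height), n)
  height_is_measured <- rep_len(as.logical(height_is_measured), n)
  trees <- data.frame(
    species_code = as.character(species_code),
    dbh = as.numeric(dbh),
    height = height,
    height_is_measured = height_is_measured,
    stringsAsFactors = FALSE
  )
  validate_tree_records(trees)
  trees
}

validate_tree_records <- function(trees) {
  if (!all(c("species_code", "dbh") %in% names(trees))) {
    stop("tree table needs at least species_code and dbh columns")
  }
  if (any(!is.finite(trees$dbh)) || any(trees$dbh <= 0)) {
    stop("dbh must be positive and finite for every tree")
  }
  h <- trees$height
  if (!is.null(h) && any(!is.na(h) & h <= BREAST_HEIGHT_M)) {
    stop("a present tree height must exceed breast height (1.37 m)")
  }
  invisible(trees)
}

clamp_ratio <- function(r) pmin(pmax(r, 0), 2)

#' Per-tree biomass from a generalized ln-ln equation
#'
#' Evaluates `biomass = exp(b0 + b1 * ln(dbh))` in kg with dbh in cm — the
#' functional form shared by the Jenkins-type and Chojnacky-type generalized
#' model sets, which differ only in their species grouping and coefficients.
#'
#' @param tree a one-row tree record (or list with `dbh`); vectors of dbh are
#'   accepted and recycled against the coefficients.
#' @param coeffs list with `b0`, `b1` (> 0) and optionally `dbh_max_sampled`.
#' @param family label recorded on the result (`"jenkins"` or `"chojnacky"`).
#' @return data.frame with columns `total` (kg), `bole`, `bark`, `branch`
#'   (NA — ln-ln models are not component-resolved), `family`, and
#'   `extrapolation_flag` (TRUE when dbh exceeds the largest destructively
#'   sampled diameter, when that is known).
#' @export
lnln_biomass <- function(tree, coeffs, family = "jenkins") {
  dbh <- tree$dbh
  if (any(!is.finite(dbh)) || any(dbh <= 0)) stop("dbh must be positive")
  if (is.null(coeffs$b0) || is.null(coeffs$b1)) {
    stop("ln-ln coefficients need b0 and b1")
  }
  if (any(coeffs$b1 <= 0)) stop("b1 must be positive")
  total <- exp(coeffs$b0 + coeffs$b1 * log(dbh))
  dmax <- coeffs$dbh_max_sampled
  flag <- if (is.null(dmax)) rep(FALSE, length(total)) else !is.na(dmax) & dbh > dmax
  data.frame(
    total = total, bole = NA_real_, bark = NA_real_, branch = NA_real_,
    family = family, extrapolation_flag = flag, stringsAsFactors = FALSE
  )
}

#' Per-tree biomass by the Component Ratio Method
#'
#' Chains merchantable stem volume through wood specific gravity and
#' component ratios: volume (m^3) from the combined-variable model
#' `V = vol_a + vol_b * dbh^2 * height` (dbh cm, height m); bole mass (kg) as
#' `V * specific_gravity * 1000`; bark and branch masses as power-of-DBH
#' ratios of the bole (`r0 * dbh^r1`, clamped to [0, 2]); total as the sum of
#' the three components.
#'
#' @param tree tree record(s) with `dbh` and a present `height`.
#' @param coeffs list with `vol_a`, `vol_b`, `bark_r0`, `bark_r1`,
#'   `branch_r0`, `branch_r1`, `specific_gravity`, optionally
#'   `dbh_max_sampled`.
#' @return data.frame with `total`, `bole`, `bark`, `branch` (kg), `family`
#'   `"crm"`, and `extrapolation_flag`.
#' @export
crm_biomass <- function(tree, coeffs) {
  dbh <- tree$dbh
  height <- tree$height
  if (any(!is.finite(dbh)) || any(dbh <= 0)) stop("dbh must be positive")
  if (is.null(height) || any(is.na(height))) {
    stop("CRM requires a tree height; impute missing heights first ",
         "(see impute_height())")
  }
  volume <- coeffs$vol_a + coeffs$vol_b * dbh^2 * height
  if (any(volume < 0)) {
    warning("negative predicted merchantable volume clamped to 0 for ",
            sum(volume < 0), " tree(s)")
    volume <- pmax(volume, 0)
  }
  bole <- volume * coeffs$specific_gravity * WATER_DENSITY_KG_M3
  bark <- bole * clamp_ratio(coeffs$bark_r0 * dbh^coeffs$bark_r1)
  branch <- bole * clamp_ratio(coeffs$branch_r0 * dbh^coeffs$branch_r1)
  dmax <- coeffs$dbh_max_sampled
  flag <- if (is.null(dmax)) rep(FALSE, length(dbh)) else !is.na(dmax) & dbh > dmax
  data.frame(
    total = bole + bark + branch, bole = bole, bark = bark, branch = branch,
    family = "crm", extrapolation_flag = flag, stringsAsFactors = FALSE
  )
}

#' Biomass for a whole tree list under one allometric family
#'
#' Resolves each tree's species through the registry and applies the family's
#' engine, preserving tree order. For `"crm"` every tree must carry a height
#' (measured or imputed).
#'
#' @param trees tree record data.frame (see [tree_records()]).
#' @param family `"jenkins"`, `"chojnacky"` or `"crm"`.
#' @param registry an `allometry_registry` covering every species in `trees`.
#' @return data.frame with the input columns plus `total`, `bole`, `bark`,
#'   `branch`, `family`, `extrapolation_flag`; the number of flagged
#'   extrapolations is attached as attribute `n_extrapolated`.
#' @export
estimate_tree_list <- function(trees, family, registry) {
  family <- match.arg(family, c("jenkins", "chojnacky", "crm"))
  validate_tree_records(trees)
  if (nrow(trees) == 0L) {
    out <- cbind(trees, data.frame(
      total = numeric(0), bole = numeric(0), bark = numeric(0),
      branch = numeric(0), family = character(0),
      extrapolation_flag = logical(0), stringsAsFactors = FALSE
    ))
    attr(out, "n_extrapolated") <- 0L
    return(out)
  }
  if (family == "crm") {
    missing_h <- which(is.na(trees$height))
    if (length(missing_h) > 0L) {
      stop("CRM requires heights; tree(s) ",
           paste(utils::head(missing_h, 5L), collapse = ", "),
           if (length(missing_h) > 5L) ", ..." else "",
           " lack one — impute first (see impute_height())")
    }
  }
  coeffs <- lookup_coefficients(registry, trees$species_code, family)
  est <- tryCatch(
    if (family == "crm") crm_biomass(trees, coeffs)
    else lnln_biomass(trees, coeffs, family = family),
    error = function(e) {
      stop("tree list estimation failed (trees 1-", nrow(trees), "): ",
           conditionMessage(e), call. = FALSE)
    }
  )
  out <- cbind(trees, est)
  attr(out, "n_extrapolated") <- sum(est$extrapolation_flag)
  out
}
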