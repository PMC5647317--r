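#' Read a species-to-group map
#'
#' The species map resolves every species code in a tree list to its Jenkins
#' group (one of 10 generalized classes), its Chojnacky group (taxonomic
#' regrouping), and a wood specific gravity used by the Component Ratio
#' Method.
#'
#' @param path delimited text file with columns `species_code`,
#'   `jenkins_group`, `chojnacky_group`, `wood_specific_gravity`.
#' @param sep field separator (default `,`).
#' @return data.frame with one row per species.
#' @export
read_species_map <- function(path, sep = ",") {
  sm <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          strip.white = TRUE)
  required <- c("species_code", "jenkins_group", "chojnacky_group",
                "wood_specific_gravity")
  missing <- setdiff(required, names(sm))
  if (length(missing) > 0L) {
    stop("species map is missing column(s): ", paste(missing, collapse = ", "))
  }
  sg <- sm$wood_specific_gravity
  if (any(!is.finite(sg)) || any(sg <= 0) || any(sg > 1.2)) {
    stop("wood specific gravity must lie in (0, 1.2]")
  }
  if (anyDuplicated(sm$species_code)) {
    stop("duplicated species_code in species map")
  }
  sm
}

#' Read an allometric coefficient registry
#'
#' Coefficients are stored as long-format delimited text with columns
#' `family`, `group_id`, `parameter`, `value` so any published regional table
#' can be loaded without code changes. Families `jenkins` and `chojnacky`
#' take ln-ln parameters `b0`, `b1` and optionally `dbh_max_sampled` (cm, the
#' largest destructively sampled stem; estimates beyond it are flagged as
#' extrapolations). Family `crm` takes combined-variable volume parameters
#' `vol_a`, `vol_b`, bark and branch ratio parameters `bark_r0`, `bark_r1`,
#' `branch_r0`, `branch_r1`, a group-default `specific_gravity`, and
#' optionally `dbh_max_sampled`.
#'
#' @param coefficients path to the long-format coefficient file (or a
#'   data.frame already in that shape).
#' @param species_map path to the species map file (or the data.frame from
#'   [read_species_map()]).
#' @param sep field separator.
#' @return an `allometry_registry` object.
#' @export
read_coefficient_registry <- function(coefficients, species_map, sep = ",") {
  if (is.character(coefficients)) {
    coefficients <- utils::read.delim(coefficients, sep = sep,
                                      stringsAsFactors = FALSE,
                                      strip.white = TRUE)
  }
  if (is.character(species_map)) {
    species_map <- read_species_map(species_map, sep = sep)
  }
  required <- c("family", "group_id", "parameter", "value")
  missing <- setdiff(required, names(coefficients))
  if (length(missing) > 0L) {
    stop("coefficient table is missing column(s): ",
         paste(missing, collapse = ", "))
  }

  widen <- function(fam, params) {
    rows <- coefficients[coefficients$family == fam, , drop = FALSE]
    if (nrow(rows) == 0L) return(NULL)
    groups <- unique(rows$group_id)
    out <- data.frame(group_id = groups, stringsAsFactors = FALSE)
    for (p in params) {
      v <- rows$value[match(paste(groups, p), paste(rows$group_id, rows$parameter))]
      out[[p]] <- v
    }
    out
  }

  lnln <- list(
    jenkins   = widen("jenkins",   c("b0", "b1", "dbh_max_sampled")),
    chojnacky = widen("chojnacky", c("b0", "b1", "dbh_max_sampled"))
  )
  crm <- widen("crm", c("vol_a", "vol_b", "bark_r0", "bark_r1",
                        "branch_r0", "branch_r1", "specific_gravity",
                        "dbh_max_sampled"))

  for (fam in names(lnln)) {
    tab <- lnln[[fam]]
    if (!is.null(tab)) {
      if (any(is.na(tab$b0)) || any(is.na(tab$b1))) {
        stop("family '", fam, "' has groups without b0/b1")
      }
      if (any(tab$b1 <= 0)) {
        stop("family '", fam, "' has non-positive slope b1 (biomass must ",
             "increase with diameter)")
      }
    }
  }
  if (!is.null(crm) && any(is.na(crm$vol_a) | is.na(crm$vol_b))) {
    stop("crm groups without volume parameters")
  }

  reg <- structure(
    list(species = species_map, lnln = lnln, crm = crm),
    class = "allometry_registry"
  )
  validate_registry(reg)
  reg
}

validate_registry <- function(registry) {
  sm <- registry$species
  check_groups <- function(fam, col) {
    tab <- registry$lnln[[fam]]
    if (is.null(tab)) return(invisible())
    unresolved <- setdiff(sm[[col]], tab$group_id)
    if (length(unresolved) > 0L) {
      stop("species map references ", fam, " group(s) without coefficients: ",
           paste(unresolved, collapse = ", "))
    }
  }
  check_groups("jenkins", "jenkins_group")
  check_groups("chojnacky", "chojnacky_group")
  if (!is.null(registry$crm)) {
    unresolved <- setdiff(sm$jenkins_group, registry$crm$group_id)
    if (length(unresolved) > 0L) {
      stop("species map references CRM group(s) without coefficients: ",
           paste(unresolved, collapse = ", "))
    }
  }
  invisible(registry)
}

#' Bundled illustrative coefficient registry
#'
#' Loads the registry shipped with the package: ln-ln coefficients for the 10
#' Jenkins-style groups and a set of Chojnacky-style taxonomic groups, plus
#' combined-variable CRM volume/ratio parameters per group, and a species map
#' for common northern-California species. The values are illustrative
#' defaults for testing and simulation; analyses of real inventories should
#' load the authoritative published tables via [read_coefficient_registry()].
#'
#' @return an `allometry_registry`.
#' @export
default_registry <- function() {
  read_coefficient_registry(
    system.file("extdata", "allometry_coefficients.csv", package = "allomap"),
    system.file("extdata", "species_map.csv", package = "allomap")
  )
}

#' @export
print.allometry_registry <- function(x, ...) {
  cat("Allometric coefficient registry\n")
  cat("  species mapped:   ", nrow(x$species), "\n")
  for (fam in names(x$lnln)) {
    if (!is.null(x$lnln[[fam]])) {
      cat(sprintf("  %-18s %d ln-ln groups\n", paste0(fam, ":"),
                  nrow(x$lnln[[fam]])))
    }
  }
  if (!is.null(x$crm)) cat("  crm:               ", nrow(x$crm), "groups\n")
  invisible(x)
}

# Resolve species -> coefficient rows -----------------------------------------

resolve_species <- function(registry, species_code) {
  idx <- match(species_code, registry$species$species_code)
  if (anyNA(idx)) {
    bad <- unique(species_code[is.na(idx)])
    stop("species code(s) not in registry: ", paste(bad, collapse = ", "))
  }
  registry$species[idx, , drop = FALSE]
}

#' Look up coefficients for one species under one family
#'
#' @param registry an `allometry_registry`.
#' @param species_code single species code present in the registry's map.
#' @param family one of `"jenkins"`, `"chojnacky"`, `"crm"`.
#' @return a named list of coefficients for the species' group; for `crm` the
#'   species-level wood specific gravity overrides the group default.
#' @export
lookup_coefficients <- function(registry, species_code, family) {
  family <- match.arg(family, c("jenkins", "chojnacky", "crm"))
  sp <- resolve_species(registry, species_code)
  if (family == "crm") {
    tab <- registry$crm
    row <- tab[match(sp$jenkins_group, tab$group_id), , drop = FALSE]
    out <- as.list(row)
    # species-level specific gravity takes precedence over the group default
    out$specific_gravity <- ifelse(is.na(sp$wood_specific_gravity),
                                   row$specific_gravity,
                                   sp$wood_specific_gravity)
    return(out)
  }
  col <- if (family == "jenkins") "jenkins_group" else "chojnacky_group"
  tab <- registry$lnln[[family]]
  if (is.null(tab)) stop("registry has no coefficients for family ", family)
  as.list(tab[match(sp[[col]], tab$group_id), , drop = FALSE])
}
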