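#' Titratable site class
#'
#' A class of identical, independently titratable side chains in the channel
#' pore (e.g. the four introduced HBC aspartates/glutamates of a homotetramer,
#' or the two ionizable residues left in a tandem-dimer construct).
#'
#' @param label Short identifying string, e.g. `"HBC-E"` or `"cavity-D"`.
#' @param n_sites Integer number of sites of this class per channel (>= 0).
#' @param K_H Proton dissociation constant of one site, in mol/L (> 0).
#'   The corresponding pKa is `-log10(K_H)`.
#' @return An object of class `"site_class"`.
#' @examples
#' site_class("HBC-E", 4, 2e-7)   # pKa ~ 6.7
#' @export
site_class <- function(label, n_sites, K_H) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (!is.numeric(n_sites) || length(n_sites) != 1L || is.na(n_sites) ||
      n_sites < 0 || n_sites != round(n_sites))
    stop("'n_sites' must be a single non-negative integer")
  if (!is.numeric(K_H) || length(K_H) != 1L || !is.finite(K_H) || K_H <= 0)
    stop("'K_H' must be a single positive finite number (mol/L)")
  structure(list(label = label, n_sites = as.integer(n_sites), K_H = K_H),
            class = "site_class")
}

#' Default monotone conductance map
#'
#' Relative conductance of the channel as a function of the total number of
#' protonated sites `k = 0..n`. For a four-site channel the default is the
#' experimentally observed G178D relative amplitude ladder, with the two
#' least-protonated states sharing the (unresolved) full amplitude; for other
#' site counts a linearly decreasing ladder from 1 is used.
#'
#' @param n_total Total number of titratable sites.
#' @return Numeric vector of length `n_total + 1`, non-increasing, starting
#'   at 1.
#' @export
default_conductance_map <- function(n_total) {
  if (n_total == 4L) {
    # k = 0..4; k = 0 and 1 both render at the full amplitude (the two top
    # model states are not separated experimentally)
    c(1.00, 1.00, 0.92, 0.74, 0.45)
  } else if (n_total == 0L) {
    1
  } else {
    seq(1, 0.45, length.out = n_total + 1L)
  }
}

#' Default aggregation of model protonation states onto experimental levels
#'
#' Maps the model's protonation count `k` (0 = fully deprotonated, most
#' conductive) onto the experimentally resolved conducting levels
#' `O1 < O2 < ... < Om` (Om = highest conductance). The default for a
#' four-site channel merges `k = 0` and `k = 1` into the top level, since
#' only four conducting states are resolved while the model has five open
#' states.
#'
#' @param n_total Total number of titratable sites.
#' @return Integer vector `a` of length `n_total + 1`; `a[k + 1]` is the
#'   experimental level index (1 = lowest conducting level).
#' @export
default_aggregation <- function(n_total) {
  if (n_total == 0L) return(1L)
  k <- 0:n_total
  if (n_total == 4L) {
    # k = 0 and k = 1 share the top level (the two most-conductive model
    # states are not separated experimentally): c(4, 4, 3, 2, 1)
    pmin.int(n_total - k + 1L, n_total)
  } else {
    n_total - k + 1L        # identity ladder, m = n_total + 1 levels
  }
}

#' Protonation-gating model parameters
#'
#' Parameter container for the non-cooperative subunit-protonation model of
#' sub-conductance gating: each titratable site is protonated independently
#' with dissociation constant `K_H`, each additional protonation lowers the
#' channel conductance one step, and every conducting state has a paired
#' brief-closed state in equilibrium `K_OC` (attributed to independent
#' selectivity-filter closures).
#'
#' @param site_classes A single [site_class()] or a list of them. Default: one
#'   class of 4 sites with `K_H = 2e-7` M (pKa ~ 6.7).
#' @param K_OC Dimensionless open to brief-closed equilibrium constant
#'   (>= 0). Default 0.05.
#' @param conductance_map Numeric vector of length `n_total + 1` mapping the
#'   total protonation count to relative conductance in `[0, 1]`;
#'   non-increasing with `conductance_map[1] = 1`. Default
#'   [default_conductance_map()].
#' @param aggregation Integer vector mapping each protonation count `k`
#'   (index `k + 1`) to an experimental conducting level (1 = lowest).
#'   Default [default_aggregation()].
#' @return An object of class `"model_params"`.
#' @examples
#' mp <- model_params()                       # the four-site HBC model
#' mp2 <- model_params(site_class("E", 2, 2e-7))  # tandem-dimer ng-nE channel
#' @export
model_params <- function(site_classes = site_class("HBC", 4L, 2e-7),
                         K_OC = 0.05,
                         conductance_map = NULL,
                         aggregation = NULL) {
  if (inherits(site_classes, "site_class")) site_classes <- list(site_classes)
  if (!is.list(site_classes) || !length(site_classes) ||
      !all(vapply(site_classes, inherits, logical(1), "site_class")))
    stop("'site_classes' must be a site_class or a list of site_class objects")
  if (!is.numeric(K_OC) || length(K_OC) != 1L || !is.finite(K_OC) || K_OC < 0)
    stop("'K_OC' must be a single finite number >= 0")
  n_total <- sum(vapply(site_classes, `[[`, integer(1), "n_sites"))
  if (is.null(conductance_map)) conductance_map <- default_conductance_map(n_total)
  if (length(conductance_map) != n_total + 1L)
    stop("'conductance_map' must have length n_total + 1 = ", n_total + 1L)
  if (any(!is.finite(conductance_map)) || any(conductance_map < 0) ||
      any(conductance_map > 1) || conductance_map[1L] != 1)
    stop("'conductance_map' entries must lie in [0, 1] with the k = 0 entry equal to 1")
  if (is.unsorted(rev(conductance_map)))
    stop("'conductance_map' must be non-increasing in the protonation count")
  if (is.null(aggregation)) aggregation <- default_aggregation(n_total)
  aggregation <- as.integer(aggregation)
  if (length(aggregation) != n_total + 1L || anyNA(aggregation) ||
      any(aggregation < 1L))
    stop("'aggregation' must assign every protonation count k = 0..", n_total,
         " a positive level index")
  structure(list(site_classes = site_classes, K_OC = K_OC,
                 conductance_map = conductance_map,
                 aggregation = aggregation, n_total = n_total),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Non-cooperative protonation gating model\n")
  for (sc in x$site_classes)
    cat(sprintf("  site class %-10s n = %d  K_H = %.4g M (pKa %.2f)\n",
                sc$label, sc$n_sites, sc$K_H, -log10(sc$K_H)))
  cat(sprintf("  K_OC = %.4g  (brief-closed fraction %.3f)\n",
              x$K_OC, x$K_OC / (1 + x$K_OC)))
  cat("  conductance map:", paste(format(x$conductance_map), collapse = " "), "\n")
  invisible(x)
}

#' Equilibrium protonation fraction of a single site
#'
#' Fraction of time one titratable site spends protonated at a given pH,
#' `f = [H+] / ([H+] + K_H)` with `[H+] = 10^(-pH)` mol/L. Monotone
#' decreasing in pH; `f = 1/2` at `pH = pKa = -log10(K_H)`.
#'
#' @param pH Acidity (vectorized). Must be finite.
#' @param K_H Proton dissociation constant, mol/L.
#' @return Protonation fraction(s) in `[0, 1]`.
#' @examples
#' site_protonation_fraction(7.4, 2e-7)          # ~0.166
#' site_protonation_fraction(-log10(2e-7), 2e-7) # exactly 0.5
#' @export
site_protonation_fraction <- function(pH, K_H) {
  if (!is.numeric(pH) || any(!is.finite(pH))) stop("'pH' must be finite")
  if (!is.numeric(K_H) || any(!is.finite(K_H)) || any(K_H <= 0))
    stop("'K_H' must be positive and finite")
  h <- 10^(-pH)
  h / (h + K_H)
}

#' Equilibrium distribution over protonation states
#'
#' Joint equilibrium probability of the total protonation count `k`, obtained
#' as the convolution of independent binomial distributions over the site
#' classes (no cooperativity), split between the conducting and the paired
#' brief-closed state via `K_OC`.
#'
#' @param params A [model_params()] object.
#' @param pH Acidity at which to evaluate.
#' @return An object of class `"state_distribution"`: list with `k` (0..n),
#'   `p_open`, `p_closed` (each summing with the other to 1), and `pH`.
#' @examples
#' sd <- state_distribution(model_params(), 7.4)
#' sum(sd$p_open) + sum(sd$p_closed)  # 1
#' @export
state_distribution <- function(params, pH) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(pH) || length(pH) != 1L || !is.finite(pH))
    stop("'pH' must be a single finite number")
  pk <- 1
  for (sc in params$site_classes) {
    if (sc$n_sites == 0L) next
    f <- site_protonation_fraction(pH, sc$K_H)
    pk <- convolve_counts(pk, stats::dbinom(0:sc$n_sites, sc$n_sites, f))
  }
  if (length(pk) < params$n_total + 1L)      # all classes empty
    pk <- c(pk, rep(0, params$n_total + 1L - length(pk)))
  w_closed <- params$K_OC / (1 + params$K_OC)
  structure(list(k = 0:params$n_total,
                 p_open = pk * (1 - w_closed),
                 p_closed = pk * w_closed,
                 pH = pH),
            class = "state_distribution")
}

# exact discrete convolution of two probability vectors over counts 0..n
convolve_counts <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Aggregate model states onto experimental conducting levels
#'
#' Collapses the per-protonation-count distribution onto the experimentally
#' resolved occupancy vector `(C, O1, ..., Om)`: the closed entry pools all
#' brief-closed states, and each conducting level pools the protonation
#' counts assigned to it by the aggregation map.
#'
#' @param dist A `"state_distribution"` from [state_distribution()].
#' @param aggregation Integer vector, `aggregation[k + 1]` = experimental
#'   level of protonation count `k` (1 = lowest conducting level). Must cover
#'   every `k` in the distribution.
#' @return Named numeric occupancy vector `c(C, O1, ..., Om)` summing to 1.
#' @export
aggregate_levels <- function(dist, aggregation) {
  stopifnot(inherits(dist, "state_distribution"))
  aggregation <- as.integer(aggregation)
  if (length(aggregation) != length(dist$k) || anyNA(aggregation) ||
      any(aggregation < 1L))
    stop("'aggregation' must assign a level to every protonation count k = 0..",
         max(dist$k))
  m <- max(aggregation)
  open <- vapply(seq_len(m), function(l) sum(dist$p_open[aggregation == l]),
                 numeric(1))
  out <- c(sum(dist$p_closed), open)
  names(out) <- c("C", paste0("O", seq_len(m)))
  out
}

#' Predict a titration table from the protonation model
#'
#' Evaluates the equilibrium occupancies of the experimental levels
#' `(C, O1..Om)` on a grid of pH values.
#'
#' @param params A [model_params()] object.
#' @param pH Numeric grid of at least 2 finite pH values.
#' @param aggregation Model-state to level map; defaults to the one stored in
#'   `params`.
#' @return A `"titration_table"`: data frame with columns `pH`, `C`,
#'   `O1`..`Om`, each occupancy row summing to 1, ordered by increasing pH.
#' @examples
#' predict_titration(model_params(), pH = seq(6, 8, 0.5))
#' @export
predict_titration <- function(params, pH, aggregation = params$aggregation) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(pH) || length(pH) < 2L || any(!is.finite(pH)))
    stop("'pH' must be a finite numeric grid with at least 2 points")
  pH <- sort(pH)
  if (anyDuplicated(pH)) stop("'pH' grid must be strictly increasing")
  occ <- t(vapply(pH,
                  function(p) aggregate_levels(state_distribution(params, p),
                                               aggregation),
                  numeric(max(aggregation) + 1L)))
  out <- data.frame(pH = pH, occ, check.names = FALSE)
  class(out) <- c("titration_table", "data.frame")
  out
}

#' Read / write occupancy-versus-pH tables
#'
#' CSV interchange format with header `pH,C,O1,...,Om[,weight]`.
#'
#' @param path File path.
#' @param x A titration table (data frame with a `pH` column, level
#'   occupancy columns, optional `weight`).
#' @return `read_titration()` returns a `"titration_table"` data frame.
#' @export
read_titration <- function(path) {
  x <- utils::read.csv(path, check.names = FALSE)
  validate_titration(x)
}

#' @rdname read_titration
#' @export
write_titration <- function(x, path) {
  x <- validate_titration(x)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_titration <- function(x, tol = 1e-6) {
  if (!is.data.frame(x) || !("pH" %in% names(x)))
    stop("titration table must be a data frame with a 'pH' column")
  lev <- setdiff(names(x), c("pH", "weight"))
  if (!("C" %in% lev) || !length(grep("^O[0-9]+$", lev)))
    stop("titration table needs a 'C' column and O1..Om columns")
  if (is.unsorted(x$pH, strictly = TRUE))
    stop("'pH' must be strictly increasing across rows")
  s <- rowSums(x[lev])
  if (any(abs(s - 1) > tol))
    stop("each occupancy row must sum to 1 (max deviation ",
         format(max(abs(s - 1))), ")")
  class(x) <- unique(c("titration_table", class(x)))
  x
}

# columns of the conducting levels + C, in canonical order C, O1..Om
level_columns <- function(x) {
  m <- sum(grepl("^O[0-9]+$", names(x)))
  c("C", paste0("O", seq_len(m)))
}

#' Read / write model parameters as JSON or YAML
#'
#' Serializes a [model_params()] object with explicit keys `site_classes`,
#' `K_OC`, `conductance_map` and `aggregation`. Format is chosen from the
#' file extension (`.json` vs `.yaml`/`.yml`).
#'
#' @param params A [model_params()] object.
#' @param path Destination/source file path.
#' @return `read_model_params()` returns a [model_params()] object.
#' @export
write_model_params <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  obj <- list(
    site_classes = lapply(params$site_classes, function(sc)
      list(label = sc$label, n_sites = sc$n_sites, K_H = sc$K_H)),
    K_OC = params$K_OC,
    conductance_map = params$conductance_map,
    aggregation = params$aggregation)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_model_params
#' @export
read_model_params <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  scs <- obj$site_classes
  if (is.data.frame(scs)) scs <- split(scs, seq_len(nrow(scs)))
  model_params(
    site_classes = lapply(scs, function(sc)
      site_class(sc$label, sc$n_sites, sc$K_H)),
    K_OC = obj$K_OC,
    conductance_map = unlist(obj$conductance_map),
    aggregation = unlist(obj$aggregation))
}
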