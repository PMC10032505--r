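# Measurement kits: grouped features that are assayed together and charged
# once per kit (e.g. a complete blood count).  Selecting any member of a kit
# incurs the whole kit's standardized price.

#' Define a kit structure
#'
#' @param kit_of named character vector mapping each feature name to its kit
#'   name; every feature belongs to exactly one kit.
#' @param kit_cost named numeric vector of nonnegative per-kit costs
#'   (standardized prices; in the bundled clinical reference table the PSA
#'   kit defines the scale with price 100).
#' @return An object of class \code{"kit_structure"}.
#' @export
kit_structure <- function(kit_of, kit_cost) {
  if (length(kit_of) == 0) {
    return(structure(list(kit_of = character(0),
                          kit_cost = numeric(0),
                          kit_names = character(0)),
                     class = "kit_structure"))
  }
  if (is.null(names(kit_of)) || any(names(kit_of) == ""))
    stop("kit_of must be a named vector: feature -> kit")
  if (anyDuplicated(names(kit_of)))
    stop("each feature may belong to exactly one kit")
  kit_of <- vapply(kit_of, as.character, character(1))
  kit_names <- unique(unname(kit_of))
  if (is.null(names(kit_cost)))
    stop("kit_cost must be a named vector: kit -> cost")
  miss <- setdiff(kit_names, names(kit_cost))
  if (length(miss))
    stop("no cost given for kit(s): ", paste(miss, collapse = ", "))
  kit_cost <- kit_cost[kit_names]
  if (any(kit_cost < 0) || any(!is.finite(kit_cost)))
    stop("kit costs must be finite and nonnegative")
  structure(list(kit_of = kit_of, kit_cost = kit_cost,
                 kit_names = kit_names),
            class = "kit_structure")
}

#' @export
print.kit_structure <- function(x, ...) {
  cat("Kit structure: ", length(x$kit_of), " features in ",
      length(x$kit_names), " kits\n", sep = "")
  invisible(x)
}

# Every feature mapped; unseen features become singleton kits of cost 0
# (the convention used for routine measurements that carry no extra charge).
complete_kits <- function(kits, feature_names) {
  extra <- setdiff(feature_names, names(kits$kit_of))
  if (length(extra) == 0) return(kits)
  add_of <- stats::setNames(extra, extra)
  add_cost <- stats::setNames(rep(0, length(extra)), extra)
  clash <- intersect(extra, names(kits$kit_cost))
  if (length(clash))
    stop("feature name(s) collide with existing kit name(s): ",
         paste(clash, collapse = ", "))
  kit_structure(c(kits$kit_of, add_of), c(kits$kit_cost, add_cost))
}

# Integer kit id per feature of `feature_names`, plus kit count
kit_index <- function(kits, feature_names) {
  kits <- complete_kits(kits, feature_names)
  ko <- kits$kit_of[feature_names]
  if (anyNA(ko)) stop("unmapped feature(s): ",
                      paste(feature_names[is.na(ko)], collapse = ", "))
  list(id = match(unname(ko), kits$kit_names),
       n_kits = length(kits$kit_names),
       kits = kits)
}

#' Read a kit-definition table
#'
#' Delimited text with header columns \code{feature}, \code{kit},
#' \code{cost}.  A kit must be given one consistent cost; duplicate
#' identical rows are deduplicated silently.  Features absent from the file
#' are later treated as singleton kits of cost 0.
#'
#' @param path file path.
#' @param sep field separator; default \code{","}.
#' @return A \code{\link{kit_structure}}.
#' @export
read_kits <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = character(0),
                          colClasses = "character")
  need <- c("feature", "kit", "cost")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("kit file missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0)
    return(kit_structure(character(0), numeric(0)))
  df$cost <- as.numeric(df$cost)
  if (anyNA(df$cost)) stop("non-numeric kit cost in file")
  df <- unique(df[, need])
  dup <- df$feature[duplicated(df$feature)]
  if (length(dup))
    stop("feature(s) mapped to more than one kit: ",
         paste(unique(dup), collapse = ", "))
  per_kit <- tapply(df$cost, df$kit, function(v) length(unique(v)))
  bad <- names(per_kit)[per_kit > 1]
  if (length(bad))
    stop("conflicting costs for kit(s): ", paste(bad, collapse = ", "))
  kit_of <- stats::setNames(df$kit, df$feature)
  kit_cost <- stats::setNames(df$cost, df$kit)[!duplicated(df$kit)]
  kit_structure(kit_of, kit_cost)
}

#' Total measurement cost of a feature set
#'
#' Each distinct kit touched by the selection is charged once; features not
#' present in the kit table are free singleton kits.
#'
#' @param selected_features character vector of feature names (possibly
#'   empty).
#' @param kits a \code{\link{kit_structure}}.
#' @return Nonnegative total cost.
#' @export
kit_cost <- function(selected_features, kits) {
  stopifnot(inherits(kits, "kit_structure"))
  selected_features <- unique(as.character(selected_features))
  if (length(selected_features) == 0) return(0)
  kits <- complete_kits(kits, selected_features)
  used <- unique(unname(kits$kit_of[selected_features]))
  sum(kits$kit_cost[used])
}

#' Number of active kits
#'
#' Counts the kits containing at least one coefficient with absolute value
#' above \code{zero_tol}.
#'
#' @param beta named numeric vector (names identify the features), or an
#'   unnamed vector together with \code{feature_names}.
#' @param kits a \code{\link{kit_structure}}.
#' @param zero_tol nonnegative threshold below which a coefficient counts
#'   as zero; default 0.
#' @param feature_names feature names if \code{beta} is unnamed.
#' @return Integer count of active kits.
#' @export
kit_l0 <- function(beta, kits, zero_tol = 0, feature_names = names(beta)) {
  stopifnot(inherits(kits, "kit_structure"), zero_tol >= 0)
  if (is.null(feature_names))
    stop("beta must be named or feature_names supplied")
  idx <- kit_index(kits, feature_names)
  active <- abs(as.numeric(beta)) > zero_tol
  length(unique(idx$id[active]))
}
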