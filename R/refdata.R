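#' Construct a computational phantom
#'
#' A phantom is a named set of source/target regions with masses (inclusive of
#' regional blood) and a total-body mass.  Region masses are in grams, as
#' exported by the common organ-level dosimetry tools.
#'
#' @param name Identifier for the phantom.
#' @param total_body_mass_g Total-body mass in grams.
#' @param regions `data.frame` with columns `region` (unique names),
#'   `mass_g` (> 0, < total body mass), and logical `is_source`, `is_target`.
#' @param species Free-text species label (e.g. `"mouse"`, `"human"`).
#'   Effective dose is only defined for human phantoms, so [effective_dose()]
#'   refuses reports computed on a phantom whose species is not human.
#' @return An object of class `predose_phantom`.
#' @export
phantom <- function(name, total_body_mass_g, regions, species = "unspecified") {
  tbm <- pd_num1(total_body_mass_g, "total_body_mass_g")
  if (tbm <= 0) pd_stop("total body mass must be > 0")
  req <- c("region", "mass_g", "is_source", "is_target")
  if (!all(req %in% names(regions))) {
    pd_format_stop(sprintf("phantom regions need columns: %s",
                           paste(setdiff(req, names(regions)), collapse = ", ")))
  }
  regions$region <- as.character(regions$region)
  if (anyDuplicated(regions$region)) {
    pd_stop(sprintf("duplicate phantom region(s): %s",
                    paste(unique(regions$region[duplicated(regions$region)]),
                          collapse = ", ")))
  }
  if (any(!is.finite(regions$mass_g)) || any(regions$mass_g <= 0)) {
    pd_stop("every phantom region mass must be a positive number")
  }
  if (any(regions$mass_g >= tbm)) {
    bad <- regions$region[regions$mass_g >= tbm]
    pd_stop(sprintf("region mass must be smaller than total-body mass: %s",
                    paste(bad, collapse = ", ")))
  }
  regions$is_source <- as.logical(regions$is_source)
  regions$is_target <- as.logical(regions$is_target)
  structure(list(name = as.character(name), species = as.character(species),
                 total_body_mass_g = tbm,
                 regions = regions[, req]),
            class = "predose_phantom")
}

#' Read a phantom definition from a CSV file
#'
#' Expected dialect: comma-delimited UTF-8, one header row, `#` comment lines
#' skipped; columns `region,mass_g,is_source,is_target` plus one row whose
#' region is `TOTALBODY` carrying the total-body mass.
#'
#' @param path Path to the phantom CSV file.
#' @param name Phantom identifier; defaults to the file name without extension.
#' @inheritParams phantom
#' @return A `predose_phantom`.
#' @export
load_phantom <- function(path, name = NULL, species = "unspecified") {
  if (!file.exists(path)) pd_format_stop(sprintf("no such file: %s", path))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("region", "mass_g", "is_source", "is_target")
  if (!all(req %in% names(df))) {
    pd_format_stop(sprintf("phantom file %s lacks column(s): %s", path,
                           paste(setdiff(req, names(df)), collapse = ", ")))
  }
  tb <- toupper(df$region) == "TOTALBODY"
  if (sum(tb) != 1L) pd_format_stop("phantom file needs exactly one TOTALBODY row")
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  phantom(name, df$mass_g[tb], df[!tb, , drop = FALSE], species = species)
}

#' Write a phantom definition to CSV
#'
#' Inverse of [load_phantom()]: numeric fields survive a round trip
#' bit-exactly (masses are serialized with 17 significant digits).
#'
#' @param x A `predose_phantom`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(x, path) {
  stopifnot(inherits(x, "predose_phantom"))
  df <- x$regions
  df <- rbind(df, data.frame(region = "TOTALBODY", mass_g = x$total_body_mass_g,
                             is_source = FALSE, is_target = FALSE))
  df$mass_g <- sprintf("%.17g", df$mass_g)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mass of a phantom region
#'
#' @param phantom A `predose_phantom`.
#' @param region Region name, or `"TOTALBODY"` for the total-body mass.
#' @return Mass in grams.
#' @export
region_mass <- function(phantom, region) {
  stopifnot(inherits(phantom, "predose_phantom"))
  if (toupper(region) == "TOTALBODY") return(phantom$total_body_mass_g)
  i <- match(region, phantom$regions$region)
  if (is.na(i)) pd_stop(sprintf("region '%s' not defined in phantom '%s'",
                                region, phantom$name))
  phantom$regions$mass_g[i]
}

#' @export
print.predose_phantom <- function(x, ...) {
  cat(sprintf("<phantom '%s' (%s), total body %.6g g, %d regions>\n",
              x$name, x$species, x$total_body_mass_g, nrow(x$regions)))
  print(x$regions, row.names = FALSE)
  invisible(x)
}

#' Construct a radionuclide description
#'
#' @param name Radionuclide identifier.
#' @param half_life_h Physical half-life in hours.
#' @param delta_np_J Mean energy emitted per decay as non-penetrating
#'   radiation (betas, electrons, alphas), in joules.  Used by the self-dose
#'   sanity check; may be 0 for a pure-photon emitter.
#' @param components Optional `data.frame` with columns `radiation_type` and
#'   `dose_fraction` partitioning the absorbed dose among radiation types
#'   (each fraction in \[0, 1\]); used for equivalent/RBE-weighted dose when
#'   the S-value table has no per-radiation-type breakdown.
#' @return An object of class `predose_nuclide` with the derived decay
#'   constant `lambda_p = ln(2) / half_life_h` (1/h).
#' @export
radionuclide <- function(name, half_life_h, delta_np_J = 0, components = NULL) {
  hl <- pd_num1(half_life_h, "half_life_h")
  if (hl <= 0) pd_stop("physical half-life must be > 0")
  dnp <- pd_num1(delta_np_J, "delta_np_J")
  if (dnp < 0) pd_stop("delta_np_J must be >= 0")
  if (!is.null(components)) {
    if (!all(c("radiation_type", "dose_fraction") %in% names(components))) {
      pd_format_stop("components need columns radiation_type, dose_fraction")
    }
    f <- components$dose_fraction
    if (any(f < 0 | f > 1)) pd_stop("radiation dose fractions must lie in [0, 1]")
    components$radiation_type <- as.character(components$radiation_type)
  }
  structure(list(name = as.character(name), half_life_h = hl,
                 lambda_p = log(2) / hl, delta_np_J = dnp,
                 components = components),
            class = "predose_nuclide")
}

#' Read radionuclide decay data from CSV
#'
#' Columns `name,half_life_h,delta_np_J,radiation_type,dose_fraction`; one row
#' per radiation type (name, half-life and delta repeated).
#'
#' @param path Path to the nuclide CSV file.
#' @param name Optional nuclide name to select when the file lists several.
#' @return A `predose_nuclide`.
#' @export
load_nuclide <- function(path, name = NULL) {
  if (!file.exists(path)) pd_format_stop(sprintf("no such file: %s", path))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("name", "half_life_h", "delta_np_J")
  if (!all(req %in% names(df))) {
    pd_format_stop(sprintf("nuclide file lacks column(s): %s",
                           paste(setdiff(req, names(df)), collapse = ", ")))
  }
  if (is.null(name)) name <- df$name[1]
  df <- df[df$name == name, , drop = FALSE]
  if (!nrow(df)) pd_stop(sprintf("nuclide '%s' not found in %s", name, path))
  if (length(unique(df$half_life_h)) != 1L) {
    pd_stop(sprintf("inconsistent half-lives for nuclide '%s'", name))
  }
  comp <- NULL
  if (all(c("radiation_type", "dose_fraction") %in% names(df)) &&
      !all(is.na(df$radiation_type))) {
    comp <- df[, c("radiation_type", "dose_fraction")]
  }
  radionuclide(name, df$half_life_h[1], df$delta_np_J[1], comp)
}

#' @export
print.predose_nuclide <- function(x, ...) {
  cat(sprintf("<radionuclide %s: T1/2 = %.6g h, lambda_p = %.6g 1/h, delta_np = %.4g J>\n",
              x$name, x$half_life_h, x$lambda_p, x$delta_np_J))
  if (!is.null(x$components)) print(x$components, row.names = FALSE)
  invisible(x)
}

#' Read an S-value matrix from CSV
#'
#' S-values are absorbed dose rates per unit activity, S(rT <- rS), in
#' Gy/(Bq s), precomputed for one phantom + radionuclide.  Expected columns:
#' `target,source,svalue_Gy_per_Bq_s` and optionally `radiation_type`
#' (default `"total"`; when per-type rows are given the total matrix is their
#' sum).  Every row must reference regions declared in `phantom`; a self-dose
#' (diagonal) entry is mandatory for every source-capable region, while
#' absent cross-fire pairs default to 0 with a warning, so sparse toy
#' matrices remain usable (self-dose dominates for non-penetrating emitters).
#'
#' @param path Path to the S-value CSV file.
#' @param phantom The `predose_phantom` the matrix belongs to.
#' @param nuclide_name Optional radionuclide label stored with the matrix.
#' @return An object of class `predose_svalues` with a dense `total` matrix
#'   (targets x sources) and, when typed rows are present, one sub-matrix per
#'   radiation type in `$by_type`.
#' @export
load_svalues <- function(path, phantom, nuclide_name = NA_character_) {
  stopifnot(inherits(phantom, "predose_phantom"))
  if (!file.exists(path)) pd_format_stop(sprintf("no such file: %s", path))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("target", "source", "svalue_Gy_per_Bq_s")
  if (!all(req %in% names(df))) {
    pd_format_stop(sprintf("S-value file lacks column(s): %s",
                           paste(setdiff(req, names(df)), collapse = ", ")))
  }
  if (!"radiation_type" %in% names(df)) df$radiation_type <- "total"
  svalue_matrix(df, phantom, nuclide_name)
}

#' Build an S-value matrix from long-format rows
#'
#' @param rows `data.frame` with columns `target,source,svalue_Gy_per_Bq_s`
#'   and optional `radiation_type`.
#' @inheritParams load_svalues
#' @return A `predose_svalues`.
#' @export
svalue_matrix <- function(rows, phantom, nuclide_name = NA_character_) {
  stopifnot(inherits(phantom, "predose_phantom"))
  if (!"radiation_type" %in% names(rows)) rows$radiation_type <- "total"
  known <- phantom$regions$region
  bad <- !(rows$target %in% known) | !(rows$source %in% known)
  if (any(bad)) {
    i <- which(bad)[1]
    pd_stop(sprintf("S-value row %d references region(s) absent from phantom '%s': %s <- %s",
                    i, phantom$name, rows$target[i], rows$source[i]))
  }
  if (any(rows$svalue_Gy_per_Bq_s < 0)) pd_stop("S-values must be >= 0")
  sources <- known[phantom$regions$is_source]
  targets <- known[phantom$regions$is_target]
  types <- unique(rows$radiation_type)
  by_type <- lapply(types, function(ty) {
    m <- matrix(0, nrow = length(targets), ncol = length(sources),
                dimnames = list(target = targets, source = sources))
    sub <- rows[rows$radiation_type == ty, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      if (!(sub$target[i] %in% targets)) {
        pd_stop(sprintf("S-value row targets '%s', which is not target-capable", sub$target[i]))
      }
      if (!(sub$source[i] %in% sources)) {
        pd_stop(sprintf("S-value row uses source '%s', which is not source-capable", sub$source[i]))
      }
      m[sub$target[i], sub$source[i]] <- m[sub$target[i], sub$source[i]] +
        sub$svalue_Gy_per_Bq_s[i]
    }
    m
  })
  names(by_type) <- types
  total <- Reduce(`+`, by_type)
  diag_regions <- intersect(sources, targets)
  listed <- paste(rows$target, rows$source)
  missing_diag <- diag_regions[!(paste(diag_regions, diag_regions) %in% listed)]
  if (length(missing_diag)) {
    pd_stop(sprintf("self-dose S-value entry required for source region(s): %s",
                    paste(missing_diag, collapse = ", ")))
  }
  n_pairs <- length(targets) * length(sources)
  n_given <- length(unique(listed))
  if (n_given < n_pairs) {
    pd_warn(sprintf("%d of %d (target, source) S-value pairs absent; defaulting them to 0",
                    n_pairs - n_given, n_pairs), class = "predose_sparse_svalues")
  }
  structure(list(phantom = phantom$name, nuclide = nuclide_name,
                 targets = targets, sources = sources,
                 total = total,
                 by_type = if (length(types) > 1L || !identical(types, "total")) by_type else NULL),
            class = "predose_svalues")
}

#' Query an S-value
#'
#' @param sv A `predose_svalues`.
#' @param target,source Region names declared in the phantom.
#' @param type Radiation type, or `"total"` for the summed matrix.
#' @return S(target <- source) in Gy/(Bq s).
#' @export
get_svalue <- function(sv, target, source, type = "total") {
  stopifnot(inherits(sv, "predose_svalues"))
  m <- if (identical(type, "total")) sv$total else {
    if (is.null(sv$by_type) || !type %in% names(sv$by_type)) {
      pd_stop(sprintf("no radiation type '%s' in S-value matrix", type))
    }
    sv$by_type[[type]]
  }
  if (!target %in% rownames(m)) pd_stop(sprintf("unknown target region '%s'", target))
  if (!source %in% colnames(m)) pd_stop(sprintf("unknown source region '%s'", source))
  m[target, source]
}

#' @export
print.predose_svalues <- function(x, ...) {
  cat(sprintf("<S-value matrix: phantom '%s', nuclide %s, %d targets x %d sources%s>\n",
              x$phantom, x$nuclide, length(x$targets), length(x$sources),
              if (is.null(x$by_type)) "" else
                sprintf(", types: %s", paste(names(x$by_type), collapse = ", "))))
  print(x$total)
  invisible(x)
}

#' Read tissue (wT) and radiation (wR) weighting factors from CSV
#'
#' Columns `kind,key,value` with `kind` one of `wT` (tissue weighting factor,
#' dimensionless, summing to 1 over the listed tissues) or `wR` (radiation
#' weighting factor, >= 1).
#'
#' @param path Path to the weights CSV file.
#' @return An object of class `predose_weights` with named numeric vectors
#'   `$wT` and `$wR`.
#' @export
load_weights <- function(path) {
  if (!file.exists(path)) pd_format_stop(sprintf("no such file: %s", path))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("kind", "key", "value") %in% names(df))) {
    pd_format_stop("weights file needs columns kind,key,value")
  }
  tissue_weights(
    wT = setNames(df$value[df$kind == "wT"], df$key[df$kind == "wT"]),
    wR = setNames(df$value[df$kind == "wR"], df$key[df$kind == "wR"])
  )
}

#' Construct a weighting-factor table
#'
#' @param wT Named numeric vector of tissue weighting factors.
#' @param wR Named numeric vector of radiation weighting factors.
#' @return A `predose_weights`.
#' @export
tissue_weights <- function(wT = numeric(), wR = numeric()) {
  if (any(wT < 0)) pd_stop("tissue weighting factors wT must be >= 0")
  if (length(wT)) {
    s <- sum(wT)
    if (s > 1 + 1e-9) pd_stop(sprintf("sum of wT = %.6g exceeds 1", s))
    if (abs(s - 1) > 1e-9) {
      pd_warn(sprintf("tissue weighting factors sum to %.6g, not 1", s),
              class = "predose_wt_sum")
    }
  }
  if (any(wR < 1 - 1e-9)) pd_stop("radiation weighting factors wR must be >= 1")
  structure(list(wT = wT, wR = wR), class = "predose_weights")
}
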