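measurement_schema <- c("species", "specimen_id", "clade", "thermo_class",
                        "body_mass_g", "skull_vol_mm3", "hull_vol_mm3",
                        "nasal_sa_mm2", "nasal_vol_mm3", "resp_sa_mm2",
                        "resp_vol_mm3")

size_columns <- measurement_schema[5:11]

#' Analysis configuration for the full comparison grid
#'
#' The default grid mirrors the study design: the whole nasal cavity
#' against body mass, skull volume and convex-hull head-model volume, and
#' the respiratory region against the two head-size proxies only (five
#' comparisons), each with surface area and volume as the response, for
#' each requested line-fitting method. Mammals are excluded from
#' respiratory-region comparisons (their respiratory/olfactory boundary
#' cannot be drawn consistently), which the pipeline enforces.
#'
#' @param methods subset of `c("ols", "sma", "pgls")`.
#' @param alpha significance level of the conditional scheme.
#' @param exclude_clades_respiratory clades dropped from respiratory-region
#'   comparisons.
#' @param mass_equation optional named list/vector with coefficients `a`,
#'   `b` of a length--mass power law used to fill missing crocodylian body
#'   masses (see [estimate_crocodylian_mass()]).
#' @param seed stored with the report for provenance.
#' @return list of class `nasallom_analysis_config`.
#' @export
analysis_config <- function(methods = c("ols", "sma", "pgls"),
                            alpha = 0.05,
                            exclude_clades_respiratory = "Mammalia",
                            mass_equation = NULL,
                            seed = 1L) {
  methods <- tolower(methods)
  bad <- setdiff(methods, c("ols", "sma", "pgls"))
  if (length(bad)) {
    abort(paste("unknown methods:", paste(bad, collapse = ", ")),
          class = "nasallom_error_config")
  }
  if (alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1)", class = "nasallom_error_config")
  }
  structure(list(methods = methods, alpha = alpha,
                 exclude_clades_respiratory = exclude_clades_respiratory,
                 mass_equation = mass_equation, seed = as.integer(seed)),
            class = "nasallom_analysis_config")
}

# the five comparisons of the study design
comparison_grid <- function() {
  tibble::tibble(
    region = c("nasal", "nasal", "nasal", "resp", "resp"),
    size_var = c("body_mass_g", "skull_vol_mm3", "hull_vol_mm3",
                 "skull_vol_mm3", "hull_vol_mm3"))
}

response_column <- function(region, response) {
  paste0(region, if (response == "surface_area") "_sa_mm2" else "_vol_mm3")
}

#' Load and validate a measurement table
#'
#' Reads the fixed-schema CSV (`species, specimen_id, clade, thermo_class,
#' body_mass_g, skull_vol_mm3, hull_vol_mm3, nasal_sa_mm2, nasal_vol_mm3,
#' resp_sa_mm2, resp_vol_mm3`), checks types and positivity, and reports
#' problems by row. A missing body mass is accepted only when the row
#' carries a positive `total_length_cm` from which an allometric mass can
#' later be estimated (crocodylians measured by length).
#'
#' @param path CSV file.
#' @param verbose print an inventory summary (species per clade, specimens
#'   per species).
#' @return validated tibble.
#' @export
load_measurements <- function(path, verbose = FALSE) {
  rec <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(measurement_schema, names(rec))
  if (length(missing)) {
    abort(paste("missing columns:", paste(missing, collapse = ", ")),
          class = "nasallom_error_schema")
  }
  for (v in size_columns) {
    if (!is.numeric(rec[[v]])) {
      abort(paste0("column '", v, "' is not numeric"),
            class = "nasallom_error_schema")
    }
    bad <- which(!is.na(rec[[v]]) & rec[[v]] <= 0)
    if (length(bad)) {
      abort(sprintf("non-positive %s in row %d (%s)", v, bad[1],
                    rec$species[bad[1]]),
            class = "nasallom_error_validation")
    }
  }
  na_mass <- which(is.na(rec$body_mass_g))
  if (length(na_mass)) {
    has_len <- "total_length_cm" %in% names(rec) &&
      all(!is.na(rec$total_length_cm[na_mass]) &
            rec$total_length_cm[na_mass] > 0)
    if (!has_len) {
      abort(sprintf(paste("row %d (%s): body mass missing and no positive",
                          "total_length_cm to estimate it from"),
                    na_mass[1], rec$species[na_mass[1]]),
            class = "nasallom_error_validation")
    }
  }
  other_na <- setdiff(size_columns, "body_mass_g")
  for (v in other_na) {
    bad <- which(is.na(rec[[v]]))
    if (length(bad)) {
      abort(sprintf("missing %s in row %d (%s)", v, bad[1],
                    rec$species[bad[1]]),
            class = "nasallom_error_validation")
    }
  }
  if (verbose) {
    inv <- dplyr::count(rec, .data$clade, name = "specimens")
    message("loaded ", nrow(rec), " specimens of ",
            dplyr::n_distinct(rec$species), " species")
    message(paste(sprintf("  %s: %d", inv$clade, inv$specimens),
                  collapse = "\n"))
  }
  tibble::as_tibble(rec)
}

#' Estimate a crocodylian body mass from a length measurement
#'
#' Applies a configured power law `mass = a * length^b`. The coefficient
#' values are supplied by the caller (they are taken from published
#' crocodylian length--mass equations, which vary by species and length
#' measure), and the provenance is the caller's to record.
#'
#' @param length length measurement (in the unit the coefficients expect).
#' @param coefficients named vector/list with elements `a` and `b`.
#' @return estimated mass in grams.
#' @examples
#' estimate_crocodylian_mass(2, c(a = 1, b = 3))  # 8
#' @export
estimate_crocodylian_mass <- function(length, coefficients) {
  if (is.null(coefficients) ||
      !all(c("a", "b") %in% names(coefficients))) {
    abort("`coefficients` must supply `a` and `b`",
          class = "nasallom_error_config")
  }
  if (any(!is.finite(length)) || any(length <= 0)) {
    abort("`length` must be positive", class = "nasallom_error_config")
  }
  coefficients[["a"]] * length^coefficients[["b"]]
}

#' Run the full endotherm-vs-ectotherm comparison grid
#'
#' Log10-transforms the measurements, expands multi-specimen species into
#' 1-Ma polytomies on the tree, runs the conditional slope-then-intercept
#' comparison for every cell of the comparison grid (five comparisons x
#' surface area / volume x requested methods), and, when fossil rows are
#' present (thermoregulatory class `NA`), places each fossil's bony-bounded
#' airway volume relative to the two groups' respiratory-region lines.
#'
#' @param records measurement tibble in the [load_measurements()] schema
#'   (plus optional fossil rows).
#' @param tree species-level `phylo` tree covering all non-fossil species.
#' @param config an [analysis_config()].
#' @return a `nasallom_report`: tibbles `comparisons` (one row per cell),
#'   `fits` (per-group fitted lines), `fossil` (placements or `NULL`), the
#'   log-transformed analysis data, and the configuration.
#' @export
run_full_analysis <- function(records, tree, config = analysis_config()) {
  records <- tibble::as_tibble(records)
  if (!"specimen_id" %in% names(records)) {
    records$specimen_id <- records$species
  }
  is_fossil <- is.na(records$thermo_class) |
    records$clade %in% "Dinosauria"
  fossil_rows <- records[is_fossil, , drop = FALSE]
  extant <- records[!is_fossil, , drop = FALSE]

  # fill missing masses from lengths when an equation is configured
  na_mass <- which(is.na(extant$body_mass_g))
  if (length(na_mass)) {
    if (is.null(config$mass_equation) ||
        !"total_length_cm" %in% names(extant)) {
      abort("missing body masses and no `mass_equation` configured",
            class = "nasallom_error_config")
    }
    extant$body_mass_g[na_mass] <- estimate_crocodylian_mass(
      extant$total_length_cm[na_mass], config$mass_equation)
  }

  missing <- setdiff(unique(extant$species), tree$tip.label)
  if (length(missing)) {
    abort(paste("species missing from the tree:",
                paste(missing, collapse = ", ")),
          class = "nasallom_error_tree")
  }
  spec_tree <- expand_conspecific_tips(
    tree, extant[, c("species", "specimen_id")])
  counts <- table(extant$species)
  extant$tip_label <- ifelse(counts[extant$species] > 1,
                             extant$specimen_id, extant$species)

  ldat <- log_transform(extant, size_columns)
  grid <- tidyr::crossing(comparison_grid(),
                          response = c("surface_area", "volume"),
                          method = config$methods)
  cells <- purrr::pmap(grid, function(region, size_var, response, method) {
    dat <- ldat
    if (region == "resp" &&
        length(config$exclude_clades_respiratory)) {
      dat <- dat[!dat$clade %in% config$exclude_clades_respiratory, ,
                 drop = FALSE]
    }
    cmp <- compare_groups(dat, size_var, response_column(region, response),
                          method = method, tree = spec_tree,
                          alpha = config$alpha, tip_col = "tip_label")
    row <- tidy(cmp)
    row$region <- region
    row$response <- response
    row$n_excluded <- nrow(ldat) - nrow(dat)
    fits <- purrr::imap(cmp$fits, function(f, grp) {
      g <- tidy(f)
      tibble::tibble(region = region, size_var = size_var,
                     response = response, method = toupper(method),
                     group = grp, slope = f$slope, intercept = f$intercept,
                     n = f$n, r_squared = f$r_squared)
    })
    list(row = row, fits = dplyr::bind_rows(fits), comparison = cmp)
  })
  comparisons <- dplyr::bind_rows(purrr::map(cells, "row"))
  fits <- dplyr::bind_rows(purrr::map(cells, "fits"))

  fossil <- NULL
  if (nrow(fossil_rows)) {
    place_method <- if ("pgls" %in% config$methods) "PGLS"
                    else toupper(config$methods[1])
    fossil <- purrr::pmap_dfr(
      tidyr::crossing(i = seq_len(nrow(fossil_rows)),
                      size_var = c("skull_vol_mm3", "hull_vol_mm3")),
      function(i, size_var) {
        fr <- fossil_rows[i, ]
        fe <- fits[fits$size_var == size_var & fits$region == "resp" &
                     fits$response == "volume" &
                     fits$method == place_method, ]
        fit_e <- as_allom_fit(fe[fe$group == "endotherm", ])
        fit_c <- as_allom_fit(fe[fe$group == "ectotherm", ])
        pl <- place_fossil(log10(fr[[size_var]]),
                           log10(fr$resp_vol_mm3), fit_e, fit_c)
        out <- tidy(pl)
        out$species <- fr$species
        out$size_var <- size_var
        out$method <- place_method
        out
      })
  }

  structure(list(comparisons = comparisons, fits = fits, fossil = fossil,
                 data = ldat, config = config,
                 n_specimens = nrow(extant),
                 n_species = dplyr::n_distinct(extant$species)),
            class = "nasallom_report")
}

# minimal allom_fit reconstructed from a fitted-line table row
as_allom_fit <- function(row) {
  new_allom_fit(row$method, row$slope, row$intercept, row$n,
                row$r_squared, NA_real_,
                matrix(NA_real_, 2, 2), df_residual = row$n - 2)
}

#' @export
print.nasallom_report <- function(x, ...) {
  cat("<nasallom_report> ", x$n_specimens, " specimens, ",
      x$n_species, " species\n", sep = "")
  print(x$comparisons[, c("comparison", "response", "method", "slope_p",
                          "intercept_p", "intercept_tested")])
  invisible(x)
}

#' Export a comparison report
#'
#' Writes `comparisons.csv` (one row per comparison cell; untested
#' intercepts rendered as an em dash), `fitted_lines.csv`, `fossil.csv`
#' when present, and `report.json` (full numeric precision).
#'
#' @param report a `nasallom_report`.
#' @param dir output directory (created if needed).
#' @param formats subset of `c("csv", "json")`.
#' @return paths of the written files, invisibly.
#' @export
export_report <- function(report, dir, formats = c("csv", "json")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if ("csv" %in% formats) {
    tab <- report$comparisons
    tab$intercept_stat <- ifelse(tab$intercept_tested,
                                 format(tab$intercept_stat, digits = 6),
                                 "—")
    tab$intercept_p <- ifelse(tab$intercept_tested,
                              format(tab$intercept_p, digits = 6), "—")
    p1 <- file.path(dir, "comparisons.csv")
    readr::write_csv(tab, p1)
    p2 <- file.path(dir, "fitted_lines.csv")
    readr::write_csv(report$fits, p2)
    paths <- c(paths, p1, p2)
    if (!is.null(report$fossil)) {
      p3 <- file.path(dir, "fossil.csv")
      readr::write_csv(report$fossil, p3)
      paths <- c(paths, p3)
    }
  }
  if ("json" %in% formats) {
    pj <- file.path(dir, "report.json")
    obj <- list(comparisons = report$comparisons, fits = report$fits,
                fossil = report$fossil,
                n_specimens = report$n_specimens,
                n_species = report$n_species,
                alpha = report$config$alpha,
                methods = report$config$methods)
    jsonlite::write_json(obj, pj, digits = NA, null = "null", na = "null")
    paths <- c(paths, pj)
  }
  invisible(paths)
}

#' Read back an exported JSON report
#'
#' @param path `report.json` written by [export_report()].
#' @return list with `comparisons`, `fits` and `fossil` tibbles.
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$comparisons <- tibble::as_tibble(obj$comparisons)
  obj$fits <- tibble::as_tibble(obj$fits)
  if (!is.null(obj$fossil) && length(obj$fossil)) {
    obj$fossil <- tibble::as_tibble(obj$fossil)
  } else {
    obj$fossil <- NULL
  }
  obj
}

#' Evaluate fitted lines on a grid of sizes
#'
#' @param report a `nasallom_report`.
#' @param x log10 size values at which to evaluate each fitted line.
#' @return tibble with one row per (line, x): predicted log10 response.
#' @export
fitted_line_table <- function(report, x) {
  tidyr::crossing(report$fits, x = x) |>
    dplyr::mutate(y = .data$intercept + .data$slope * .data$x)
}
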