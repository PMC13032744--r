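#' Animal-averaged group summaries
#'
#' Implements the nesting-aware aggregation used throughout the analysis:
#' spine-level values are first averaged within animal (within each
#' grouping-cell), then the group mean is the unweighted mean of those
#' animal means, so animals with many spines do not dominate. Infinite
#' sentinel values (e.g. relative changes from silent-then-active spines)
#' are excluded from means and counted.
#'
#' @param data spine-level data.frame.
#' @param value name of the value column.
#' @param grouping character vector of grouping columns (may be empty).
#' @param animal name of the animal id column.
#' @return list with `groups` (one row per grouping cell: `mean` of animal
#'   means, `n_animals`, `n_spines`, `n_excluded_infinite`) and `animals`
#'   (the per-animal means).
#' @export
animal_averages <- function(data, value, grouping = character(0),
                            animal = "animal") {
  missing_cols <- setdiff(c(value, grouping, animal), names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  v <- data[[value]]
  inf <- is.infinite(v)
  keep <- is.finite(v)
  key_animal <- interaction(c(data[grouping], data[animal]), drop = TRUE, sep = "|")
  d <- data[keep, , drop = FALSE]
  an <- aggregate(d[[value]],
                  by = c(d[grouping], d[animal],
                         list(.cell = droplevels(key_animal[keep]))),
                  FUN = mean)
  names(an)[names(an) == "x"] <- "animal_mean"
  an$.cell <- NULL
  if (length(grouping)) {
    gkey <- interaction(an[grouping], drop = TRUE, sep = "|")
    gkey_all <- interaction(data[grouping], drop = TRUE, sep = "|")
  } else {
    gkey <- factor(rep("all", nrow(an)))
    gkey_all <- factor(rep("all", nrow(data)))
  }
  groups <- do.call(rbind, lapply(levels(gkey), function(lv) {
    rows <- an[gkey == lv, , drop = FALSE]
    allrows <- gkey_all == lv
    cbind(rows[1, grouping, drop = FALSE],
          data.frame(mean = mean(rows$animal_mean),
                     n_animals = nrow(rows),
                     n_spines = sum(allrows & keep),
                     n_excluded_infinite = sum(allrows & inf)))
  }))
  rownames(groups) <- NULL
  list(groups = groups, animals = an)
}

#' Tukey ladder-of-powers transform towards normality
#'
#' Shifts the sample to strict positivity if needed, then selects the
#' exponent lambda on a fixed grid that maximises the Shapiro-Wilk W
#' statistic of the transformed sample. The transform is the ladder of
#' powers: `x^lambda` for `lambda > 0`, `log(x)` at 0, and `-x^lambda` for
#' `lambda < 0` (sign flip keeps the map increasing), so ranks are always
#' preserved.
#'
#' @param x numeric vector (length >= 3, non-constant, finite values only).
#' @param lambdas candidate exponents.
#' @return list with `values` (transformed), `lambda`, `shift` (amount added
#'   before transforming) and `W` (Shapiro-Wilk statistic at the optimum).
#' @export
tukey_ladder_transform <- function(x, lambdas = seq(-2, 2, by = 0.25)) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  if (length(x) < 3 || length(unique(x)) == 1)
    stop("need a non-constant sample of at least 3 values")
  shift <- if (min(x) <= 0) -min(x) + diff(range(x)) / 100 else 0
  xs <- x + shift
  sw_sample <- if (length(xs) > 5000) {
    xs[round(seq(1, length(xs), length.out = 5000))]
  } else xs
  apply_lambda <- function(v, l) {
    if (l > 0) v^l else if (l == 0) log(v) else -(v^l)
  }
  W <- vapply(lambdas, function(l) {
    tv <- apply_lambda(sw_sample, l)
    if (length(unique(signif(tv, 12))) < 3) return(-Inf)
    tryCatch(shapiro.test(tv)$statistic, error = function(e) -Inf)
  }, numeric(1))
  best <- which.max(W)
  list(values = apply_lambda(xs, lambdas[best]), lambda = lambdas[best],
       shift = shift, W = W[best])
}

#' Hierarchical permutation test for a two-level treatment factor
#'
#' Inference that respects the nesting of spines within slices within
#' animals: the observed statistic is the difference of animal-averaged
#' group means (see [animal_averages()]); the null distribution is built by
#' permuting treatment labels at the exchangeable-unit level - slices within
#' animal by default, so labels are shuffled among each animal's slices, or
#' whole animals. A design check refuses factors that vary within an
#' exchange unit, since permuting such labels would break exchangeability.
#'
#' @param data spine-level data.frame.
#' @param value value column name.
#' @param group two-level factor column name.
#' @param animal,slice nesting column names.
#' @param exchange `"slice"` (permute slice labels within animal) or
#'   `"animal"` (permute animal labels).
#' @param n_perm number of permutations.
#' @param seed optional RNG seed.
#' @return list with `p_value`, `observed` (level2 mean - level1 mean),
#'   `n_perm`, `levels`, `perm_stats`.
#' @export
hierarchical_permutation_test <- function(data, value, group,
                                          animal = "animal", slice = "slice",
                                          exchange = c("slice", "animal"),
                                          n_perm = 1000L, seed = NULL) {
  exchange <- match.arg(exchange)
  need <- c(value, group, animal, if (exchange == "slice") slice)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  g <- factor(data[[group]])
  if (nlevels(g) != 2L) stop("group must have exactly two levels")
  unit <- if (exchange == "slice") data[[slice]] else data[[animal]]
  # design check: the factor must be constant within each exchange unit
  per_unit <- tapply(as.integer(g), unit, function(v) length(unique(v)))
  if (any(per_unit > 1))
    stop("treatment varies within an exchange unit; permuting at this ",
         "stratum would violate exchangeability")
  unit_tab <- unique(data.frame(unit = unit, g = g,
                                animal = data[[animal]]))
  if (any(table(unit_tab$g) < 2))
    stop("need at least 2 exchange units per arm")
  # the statistic only needs per-unit sums and counts of finite values, so
  # precompute them once and evaluate each permutation on the unit table
  v <- data[[value]]
  ok <- is.finite(v)
  u_sum <- tapply(v[ok], factor(unit[ok], levels = unit_tab$unit), sum,
                  default = 0)
  u_n <- tapply(rep(1, sum(ok)), factor(unit[ok], levels = unit_tab$unit),
                sum, default = 0)
  u_sum[is.na(u_sum)] <- 0; u_n[is.na(u_n)] <- 0
  animals <- unique(unit_tab$animal)
  a_rows <- lapply(animals, function(a) which(unit_tab$animal == a))
  stat <- function(glab) {
    lev2 <- glab == levels(g)[2]
    m1 <- m2 <- numeric(0)
    for (rows in a_rows) {
      i2 <- rows[lev2[rows]]; i1 <- rows[!lev2[rows]]
      if (sum(u_n[i1]) > 0) m1 <- c(m1, sum(u_sum[i1]) / sum(u_n[i1]))
      if (sum(u_n[i2]) > 0) m2 <- c(m2, sum(u_sum[i2]) / sum(u_n[i2]))
    }
    mean(m2) - mean(m1)
  }
  observed <- stat(unit_tab$g)
  perm_stats <- vapply(seq_len(n_perm), function(p) {
    new_lab <- unit_tab$g
    if (exchange == "slice") {
      for (rows in a_rows) new_lab[rows] <- new_lab[rows[sample.int(length(rows))]]
    } else {
      new_lab <- new_lab[sample.int(nrow(unit_tab))]
    }
    stat(new_lab)
  }, numeric(1))
  p_value <- (1 + sum(abs(perm_stats) >= abs(observed) - 1e-12)) / (1 + n_perm)
  list(p_value = p_value, observed = observed, n_perm = n_perm,
       levels = levels(g), perm_stats = perm_stats)
}

#' Convert a mass concentration to picomolar
#'
#' `pg/mL` divided by molar mass in `g/mol` is `pmol/mL`; multiplying by
#' 1000 mL/L gives `pmol/L` (pM) exactly - the conversion used to report
#' amyloid-beta ELISA concentrations.
#'
#' @param mass_conc concentration in pg/mL (> 0).
#' @param molar_mass molar mass in g/mol (> 0). Average isotopic masses of
#'   the common analytes: amyloid-beta 1-40, 4329.8 g/mol; amyloid-beta
#'   1-42, 4514.1 g/mol.
#' @param digits optional rounding of the result.
#' @return molar concentration in pM.
#' @export
pg_per_ml_to_pM <- function(mass_conc, molar_mass, digits = NULL) {
  if (any(mass_conc <= 0) || any(molar_mass <= 0))
    stop("concentration and molar mass must be positive")
  out <- 1000 * mass_conc / molar_mass
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Write the summary report for an analysed spine table
#'
#' Produces deterministic per-group summary CSVs (event rates by treatment
#' and session, relative rate change by treatment and survival, per-dendrite
#' survival fractions by astrocyte proximity and treatment, and - when PsVue
#' columns are present - PsVue relative change by treatment, survival and
#' proximity) plus simple overview figures.
#'
#' @param spines analysed spine table (output of [analyze_spine_dataset()]
#'   merged with metadata): must contain `animal`, `dendrite`, `treatment`,
#'   `survived`, `proximal`, `rate_pre`, `rate_post`; PsVue columns
#'   `psvue_pre`, `psvue_post` are optional.
#' @param out_dir output directory (created if needed).
#' @param figures write PNG figures as well as CSVs.
#' @return invisibly, the paths written.
#' @export
build_report <- function(spines, out_dir, figures = TRUE) {
  need <- c("animal", "dendrite", "treatment", "survived", "proximal",
            "rate_pre", "rate_post")
  missing_cols <- setdiff(need, names(spines))
  if (length(missing_cols))
    stop("report stage missing upstream columns: ",
         paste(missing_cols, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, file) {
    path <- file.path(out_dir, file)
    write.csv(df, path, row.names = FALSE)
    paths <<- c(paths, path)
  }
  spines$rel_change_hz <- relative_change(spines$rate_pre,
                                          spines$rate_post)$rel_change
  long <- rbind(data.frame(spines, session = "PRE", rate = spines$rate_pre),
                data.frame(spines, session = "POST", rate = spines$rate_post))
  wr(animal_averages(long, "rate", c("treatment", "session"))$groups,
     "summary_rates.csv")
  wr(animal_averages(spines, "rel_change_hz",
                     c("treatment", "survived"))$groups,
     "summary_rate_change_by_survival.csv")
  surv <- survival_by_proximity(spines)
  surv$treatment <- spines$treatment[match(surv$dendrite, spines$dendrite)]
  wr(surv, "summary_survival_by_proximity.csv")
  loss <- do.call(rbind, lapply(split(spines, spines$dendrite), function(d) {
    data.frame(dendrite = d$dendrite[1], treatment = d$treatment[1],
               animal = d$animal[1],
               percent_loss = percent_spine_loss(as.logical(d$survived)),
               n_day1 = nrow(d))
  }))
  rownames(loss) <- NULL
  wr(loss, "summary_spine_loss.csv")
  has_psvue <- all(c("psvue_pre", "psvue_post") %in% names(spines))
  if (has_psvue) {
    spines$rel_change_psvue <- relative_change(spines$psvue_pre,
                                               spines$psvue_post)$rel_change
    wr(animal_averages(spines, "rel_change_psvue",
                       c("treatment", "survived", "proximal"))$groups,
       "summary_psvue_change.csv")
  }
  if (figures) {
    fig <- file.path(out_dir, "figures.png")
    png(fig, width = 1600, height = 500 * (2 + has_psvue), res = 150)
    par(mfrow = c(2 + has_psvue, 1), mar = c(8, 4, 2, 1))
    rates <- animal_averages(long, "rate", c("treatment", "session"))$groups
    barplot(rates$mean, names.arg = paste(rates$treatment, rates$session),
            las = 2, ylab = "event rate (Hz)", main = "Animal-averaged rates")
    sv <- stats::aggregate(cbind(surv_proximal, surv_nonproximal) ~ treatment,
                           data = surv, FUN = mean, na.rm = TRUE,
                           na.action = stats::na.pass)
    barplot(t(as.matrix(sv[, -1])), beside = TRUE, names.arg = sv$treatment,
            las = 2, ylab = "survival fraction",
            legend.text = c("proximal", "non-proximal"),
            main = "Spine survival by astrocyte proximity")
    if (has_psvue) {
      ps <- animal_averages(spines, "rel_change_psvue",
                            c("treatment", "survived"))$groups
      barplot(ps$mean,
              names.arg = paste(ps$treatment,
                                ifelse(ps$survived == 1, "survived", "lost")),
              las = 2, ylab = expression(Delta * PsVue / PsVue),
              main = "PsVue change by treatment and spine fate")
    }
    dev.off()
    paths <- c(paths, fig)
  }
  invisible(paths)
}
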