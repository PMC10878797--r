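#' Synthetic survey configuration
#'
#' Parameters of the synthetic herbivory survey generator, emulating the
#' standardized survey design of roughly 30 conspecific plants with ten
#' leaves each, damage visually estimated at 0.5% resolution.  Two optional
#' non-neutral contaminations are available: `plant_sigma` mixes the attack
#' rate across plants with a mean-1 lognormal multiplier (plant-level
#' heterogeneity, inflating among-plant variability), and `regularize`
#' shrinks every damaged leaf's value toward its plant's mean positive
#' damage by the given factor (a compensation/induced-defence caricature,
#' regularizing within-plant damage).  Both are this package's own
#' constructions for
#' injecting known deviation signatures, not mechanistic herbivory models.
#'
#' @param n_plants Plants per survey (default 30).
#' @param leaves_per_plant Leaves per plant; scalar or vector of length
#'   `n_plants` (default 10).
#' @param lam Base attack rate per leaf (default 2, giving mean leaf damage
#'   of a few percent under the default event bounds).
#' @param plant_sigma SD of the lognormal plant-level rate multiplier
#'   (0 = neutral).
#' @param regularize Within-plant event-thinning probability in `[0, 1)`
#'   (0 = neutral).
#' @param record_resolution Recording resolution (default 0.005 = 0.5%).
#' @param round If `FALSE`, keep continuous damage values (no rounding).
#' @param survey_id Identifier written into the table.
#' @param seed Optional integer seed.
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(n_plants = 30, leaves_per_plant = 10, lam = 2,
                         plant_sigma = 0, regularize = 0,
                         record_resolution = 0.005, round = TRUE,
                         survey_id = "S1", seed = NULL) {
  stopifnot(n_plants >= 1, all(leaves_per_plant >= 1), lam >= 0,
            plant_sigma >= 0, regularize >= 0, regularize < 1,
            record_resolution > 0)
  structure(list(n_plants = as.integer(n_plants),
                 leaves_per_plant = as.integer(leaves_per_plant),
                 lam = lam, plant_sigma = plant_sigma,
                 regularize = regularize,
                 record_resolution = record_resolution, round = round,
                 survey_id = as.character(survey_id), seed = seed),
            class = "synth_config")
}

# round recorded damage to the survey resolution; positive values are
# floored at the resolution (an observer never records 0 for visible
# damage) and exact zeros are untouched
.record_damage <- function(x, res, round) {
  if (!round) return(x)
  pos <- x > 0
  x[pos] <- pmin(1, pmax(res, round(x[pos] / res) * res))
  x
}

#' Generate a synthetic herbivory survey
#'
#' Each plant draws a rate multiplier (1 under neutrality); each of its
#' leaves draws a Poisson number of feeding events at the plant's rate and
#' sums independent truncated-Pareto event damages, truncated at 1.  Under
#' `regularize > 0`, every damaged leaf's value is then shrunk toward the
#' plant's mean positive damage by that factor, evening out within-plant
#' damage while leaving undamaged leaves (and hence the zero fraction that
#' anchors the attack-rate estimate) untouched.  Damage is then recorded at
#' the survey resolution.
#'
#' @param cfg A [synth_config()].
#' @param event An [event_params()] object.
#' @return A `data.frame` with columns `survey_id`, `plant_id`, `leaf_id`,
#'   `prop_damage` (the survey table format used throughout the package).
#' @export
generate_survey <- function(cfg, event = event_params()) {
  stopifnot(inherits(cfg, "synth_config"))
  event <- as_event_params(event)
  P <- cfg$n_plants
  Lv <- rep(cfg$leaves_per_plant, length.out = P)
  with_seed(cfg$seed, {
    mult <- if (cfg$plant_sigma > 0)
      stats::rlnorm(P, -cfg$plant_sigma^2 / 2, cfg$plant_sigma)
    else rep(1, P)
    rows <- vector("list", P)
    for (p in seq_len(P)) {
      L <- Lv[p]
      k <- stats::rpois(L, cfg$lam * mult[p])
      total <- sum(k)
      dmg <- numeric(L)
      if (total > 0) {
        phis <- event_quantile(stats::runif(total), event)
        leaf_of <- rep.int(seq_len(L), k)
        s <- rowsum(phis, leaf_of)
        dmg[as.integer(rownames(s))] <- s[, 1L]
        dmg <- pmin(dmg, 1)
        if (cfg$regularize > 0) {
          pos <- dmg > 0
          if (sum(pos) > 1)
            dmg[pos] <- mean(dmg[pos]) +
              (1 - cfg$regularize) * (dmg[pos] - mean(dmg[pos]))
        }
      }
      dmg <- .record_damage(dmg, cfg$record_resolution, cfg$round)
      rows[[p]] <- data.frame(survey_id = cfg$survey_id, plant_id = p,
                              leaf_id = seq_len(L), prop_damage = dmg)
    }
    do.call(rbind, rows)
  })
}

#' Generate several independent surveys
#'
#' Convenience wrapper producing `n_surveys` surveys with ids `S1..Sn`;
#' survey `i` uses seed `seed + i - 1` so the whole batch is reproducible
#' from one seed.
#'
#' @param n_surveys Number of surveys.
#' @param cfg A [synth_config()]; its `survey_id` and `seed` are overridden
#'   per survey.
#' @param event An [event_params()] object.
#' @param seed Integer base seed.
#' @return A single survey table (row-bound).
#' @export
generate_surveys <- function(n_surveys, cfg, event = event_params(),
                             seed = 1) {
  out <- vector("list", n_surveys)
  for (i in seq_len(n_surveys)) {
    cfg_i <- cfg
    cfg_i$survey_id <- sprintf("S%d", i)
    cfg_i$seed <- seed + i - 1L
    out[[i]] <- generate_survey(cfg_i, event)
  }
  do.call(rbind, out)
}

#' Inclusion filters for survey tables
#'
#' Surveys contribute to among-plant analyses only with at least
#' `min_plants` plant records; plants contribute to among-leaf analyses
#' only with at least `min_leaves` leaf records.  Every exclusion is
#' logged with its reason.
#'
#' @param table A survey table.
#' @param min_plants,min_leaves Inclusion thresholds (defaults 15 and 10).
#' @return A list: `among_plant` (table restricted to qualifying surveys),
#'   `among_leaf` (table restricted to qualifying plants), `log` (a
#'   `data.frame` of exclusions with columns `level`, `id`, `reason`).
#' @export
apply_inclusion_filters <- function(table, min_plants = 15,
                                    min_leaves = 10) {
  if (nrow(table) == 0) {
    empty_log <- data.frame(level = character(), id = character(),
                            reason = character())
    return(list(among_plant = table, among_leaf = table, log = empty_log))
  }
  key <- interaction(table$survey_id, table$plant_id, drop = TRUE)
  leaves_per_plant <- table(key)
  plants_per_survey <- tapply(table$plant_id, table$survey_id,
                              function(p) length(unique(p)))
  log <- list()
  bad_surveys <- names(plants_per_survey)[plants_per_survey < min_plants]
  for (s in bad_surveys)
    log[[length(log) + 1L]] <- data.frame(
      level = "survey", id = s,
      reason = sprintf("only %d plant records (< %d) for among-plant analysis",
                       plants_per_survey[[s]], min_plants))
  bad_plants <- names(leaves_per_plant)[leaves_per_plant < min_leaves]
  for (p in bad_plants)
    log[[length(log) + 1L]] <- data.frame(
      level = "plant", id = p,
      reason = sprintf("only %d leaf records (< %d) for among-leaf analysis",
                       leaves_per_plant[[p]], min_leaves))
  list(among_plant = table[!(table$survey_id %in% bad_surveys), ,
                           drop = FALSE],
       among_leaf = table[!(key %in% bad_plants), , drop = FALSE],
       log = if (length(log)) do.call(rbind, log)
             else data.frame(level = character(), id = character(),
                             reason = character()))
}

#' Plant-level damage and survey leaf counts
#'
#' Plant damage is the arithmetic mean of the plant's sampled leaves.
#' `median_leaves` returns, per survey, the median leaf count across
#' plants (non-integer medians rounded half up), the `L` used to rescale
#' event bounds at the plant scale.
#'
#' @param table A survey table.
#' @return `plant_means`: a `data.frame` with columns `survey_id`,
#'   `plant_id`, `n_leaves`, `damage`.  `median_leaves`: a named numeric
#'   vector of `L` per survey.
#' @export
plant_means <- function(table) {
  agg <- stats::aggregate(prop_damage ~ survey_id + plant_id, data = table,
                          FUN = mean)
  cnt <- stats::aggregate(prop_damage ~ survey_id + plant_id, data = table,
                          FUN = length)
  out <- merge(agg, cnt, by = c("survey_id", "plant_id"),
               suffixes = c("", ".n"))
  names(out)[names(out) == "prop_damage"] <- "damage"
  names(out)[names(out) == "prop_damage.n"] <- "n_leaves"
  out[order(out$survey_id, out$plant_id),
      c("survey_id", "plant_id", "n_leaves", "damage")]
}

#' @rdname plant_means
#' @export
median_leaves <- function(table) {
  pm <- plant_means(table)
  vapply(split(pm$n_leaves, pm$survey_id),
         function(nl) floor(stats::median(nl) + 0.5), numeric(1))
}

#' Read and write survey tables as CSV
#'
#' The on-disk format is a UTF-8 CSV with a header row and columns
#' `survey_id`, `plant_id`, `leaf_id`, `prop_damage` (proportions in
#' `[0, 1]`); extra columns are passed through untouched.  `read_survey`
#' validates the schema and reports offending rows.
#'
#' @param table A survey table.
#' @param path File path.
#' @param percent If `TRUE`, `prop_damage` in the file is a percentage and
#'   is divided by 100 on import.
#' @return `read_survey` returns the validated `data.frame`;
#'   `write_survey` returns `path` invisibly.
#' @export
read_survey <- function(path, percent = FALSE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("survey_id", "plant_id", "leaf_id", "prop_damage")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("survey table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (percent) tab$prop_damage <- tab$prop_damage / 100
  bad <- which(!is.finite(tab$prop_damage) | tab$prop_damage < 0 |
                 tab$prop_damage > 1)
  if (length(bad))
    stop("prop_damage outside [0, 1] at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  key <- paste(tab$survey_id, tab$plant_id, tab$leaf_id)
  if (anyDuplicated(key))
    stop("duplicate (survey_id, plant_id, leaf_id) at row(s): ",
         paste(utils::head(which(duplicated(key)), 10), collapse = ", "),
         call. = FALSE)
  tab
}

#' @rdname read_survey
#' @export
write_survey <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
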