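# Hand-built fixture datasets, constructed in code at test time.

# Two ecosystems, two units, three indicators; point-mass elicitations so
# downstream results are exactly computable by hand.
make_toy_dataset <- function() {
  units <- data.frame(
    unit_id = rep(c("u1", "u2"), each = 2),
    ecosystem_id = rep(c("forest", "mountain"), 2),
    total_area = rep(c(100, 300), each = 2),
    ecosystem_area = c(60, 40, 180, 120))
  meta <- data.frame(
    indicator_id = c("moose", "ptarmigan", "ptarmigan", "lichen"),
    ecosystem_id = c("forest", "mountain", "forest", "mountain"),
    membership = c(1, 0.7, 0.3, 1),
    group_id = c("top_predator_generalist", "intermediate_predator_generalist",
                 "intermediate_predator_generalist",
                 "primary_producer_specialist"),
    extra_representative = FALSE)
  refs <- expand.grid(indicator_id = c("moose", "ptarmigan", "lichen"),
                      unit_id = c("u1", "u2"), stringsAsFactors = FALSE)
  refs <- merge(refs, data.frame(
    indicator_id = c("moose", "ptarmigan", "ptarmigan", "lichen"),
    ecosystem_id = c("forest", "mountain", "forest", "mountain")))
  refs$ref_value <- 50
  refs$definition_tag <- "pristine"
  refs$scaling_model <- "minimal"
  records <- data.frame(
    indicator_id = c("moose", "ptarmigan", "lichen"),
    ecosystem_id = c("forest", "mountain", "mountain"),
    unit_id = c("u1", "u1", "u2"),
    date = 2010L,
    mean_value = c(25, 50, 10), q25 = c(25, 50, 10), q75 = c(25, 50, 10),
    source = c("monitoring", "expert", "expert"),
    variable_kind = "continuous")
  ni_dataset(records, refs, meta, units)
}

# Dataset where every observation is a point mass at value * ref so scaled
# values are exact constants; one ecosystem, one unit per value.
make_constant_dataset <- function(values, ref = 50, dates = 2010L,
                                  groups = paste0("g", seq_along(values))) {
  n <- length(values)
  ids <- sprintf("i%02d", seq_len(n))
  units <- data.frame(unit_id = "u1", ecosystem_id = "eco",
                      total_area = 100, ecosystem_area = 100)
  meta <- data.frame(indicator_id = ids, ecosystem_id = "eco",
                     membership = 1, group_id = groups,
                     extra_representative = FALSE)
  refs <- data.frame(indicator_id = ids, ecosystem_id = "eco",
                     unit_id = "u1", ref_value = ref,
                     definition_tag = "pristine",
                     scaling_model = "minimal")
  records <- do.call(rbind, lapply(dates, function(t)
    data.frame(indicator_id = ids, ecosystem_id = "eco", unit_id = "u1",
               date = t, mean_value = values * ref, q25 = values * ref,
               q75 = values * ref, source = "expert",
               variable_kind = "continuous")))
  ni_dataset(records, refs, meta, units)
}

# Deterministic grid of elicitation triples for the fitting oracle checks.
make_fit_triples <- function(n_cont = 25, n_disc = 25, seed = 2024) {
  set.seed(seed)
  cont <- data.frame(
    mean = exp(runif(n_cont, log(0.5), log(500))),
    spread = runif(n_cont, 0.02, 0.6),
    skew = runif(n_cont, -0.3, 0.6))
  cont$q25 <- cont$mean * (1 - cont$spread * (1 - cont$skew / 2))
  cont$q75 <- cont$mean * (1 + cont$spread * (1 + cont$skew / 2))
  cont$kind <- "continuous"
  disc_mean <- exp(runif(n_disc, log(0.8), log(60)))
  disc <- data.frame(
    mean = disc_mean,
    q25 = pmax(floor(disc_mean * runif(n_disc, 0.55, 0.95)), 0),
    q75 = ceiling(disc_mean * runif(n_disc, 1.05, 1.6)))
  disc$spread <- NA; disc$skew <- NA
  disc$kind <- "discrete"
  rbind(cont[, c("mean", "q25", "q75", "kind")],
        disc[, c("mean", "q25", "q75", "kind")])
}
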