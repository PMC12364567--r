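# Seeded generators producing inputs with the statistical structure the
# pipeline assumes: (a) multi-compartment presence data with planted
# A/U/B/N2/PARTIAL variables and Bernoulli detection dropout; (b) a serum
# cohort with sex effects on lipid abundances, optionally confounded with
# a BMI covariate. Truth tables are returned beside the data so recovery
# can be scored.

#' Plant a traffic truth table
#'
#' Builds a per-variable planted localization for each phenotype: for each
#' requested type, variables are assigned a compartment set consistent with
#' the type (A = all nodes, U = one node, B = an adjacent pair, N2 = a
#' non-adjacent pair, PARTIAL = a random set of size 3..(nodes-1)). The
#' same localization is planted for every phenotype (phenotype contrasts
#' are introduced by editing the truth table or by dropout).
#'
#' @param network A [compartment_network()].
#' @param n_per_type Named integer vector, e.g. \code{c(A = 10, U = 10,
#'   B = 10, N2 = 10)}; names among A, U, B, N2, PARTIAL. N2 requires the
#'   network to have at least one non-adjacent pair; B at least one edge.
#' @param phenotypes Character vector of phenotype labels.
#' @param class_pool Lipid classes to draw variable names from.
#' @param seed Integer seed.
#' @return A data.frame: variable, phenotype, planted_label,
#'   planted_compartments (";"-joined).
#' @export
plant_traffic_truth <- function(network, n_per_type, phenotypes = c("F", "M"),
                                class_pool = c("PC", "TG"), seed = 1L) {
  stopifnot(inherits(network, "compartment_network"))
  bad <- setdiff(names(n_per_type), c("A", "U", "B", "N2", "PARTIAL"))
  if (length(bad) > 0L) stop("unknown planted type(s): ", paste(bad, collapse = ", "))
  nodes <- network$nodes
  pairs <- t(utils::combn(sort(nodes), 2L))
  adj <- apply(pairs, 1L, function(pr) has_edge(network, pr[1L], pr[2L]))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  total <- sum(n_per_type)
  # distinct plausible names: CLASS(C:D)
  combos <- expand.grid(class = class_pool, c = seq(30L, 59L), d = 0:9,
                        stringsAsFactors = FALSE)
  if (total > nrow(combos)) stop("too many variables requested for the name pool")
  picks <- combos[sample.int(nrow(combos), total), ]
  vnames <- paste0(picks$class, "(", picks$c, ":", picks$d, ")")

  loc_for <- function(type) {
    switch(type,
      A = nodes,
      U = sample(nodes, 1L),
      B = { if (!any(adj)) stop("network has no edges; cannot plant B")
            pairs[sample(which(adj), 1L), ] },
      N2 = { if (all(adj)) stop("network has no non-adjacent pair; cannot plant N2")
             pairs[sample(which(!adj), 1L), ] },
      PARTIAL = { if (length(nodes) < 4L) stop("PARTIAL needs >= 4 nodes")
                  sample(nodes, sample(3:(length(nodes) - 1L), 1L)) })
  }
  rows <- list(); i <- 0L
  for (type in names(n_per_type)) {
    for (k in seq_len(n_per_type[[type]])) {
      i <- i + 1L
      loc <- sort(loc_for(type))
      for (p in phenotypes)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = vnames[i], phenotype = p, planted_label = type,
          planted_compartments = paste(loc, collapse = ";"),
          stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulation settings for a traffic dataset
#'
#' @param network A [compartment_network()].
#' @param truth A [plant_traffic_truth()] table (or an edited one).
#' @param n_per_group Samples per (phenotype, compartment) cell; >= 3
#'   (fewer cannot exercise the 66\% occupancy rule). Default 8.
#' @param meanlog,sdlog Log-normal signal parameters where a variable is
#'   planted present.
#' @param dropout Probability in [0, 1) that a truly-present sample records
#'   zero (independent Bernoulli per sample).
#' @param seed Integer seed.
#' @return A \code{traffic_sim_spec} list.
#' @export
traffic_sim_spec <- function(network, truth, n_per_group = 8L,
                             meanlog = 4, sdlog = 0.5, dropout = 0,
                             seed = 1L) {
  stopifnot(inherits(network, "compartment_network"))
  if (n_per_group < 3L) stop("n_per_group must be >= 3")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  structure(list(network = network, truth = truth,
                 n_per_group = as.integer(n_per_group), meanlog = meanlog,
                 sdlog = sdlog, dropout = dropout, seed = as.integer(seed)),
            class = "traffic_sim_spec")
}

#' Generate a multi-compartment abundance dataset with planted traffic
#'
#' For every variable, phenotype and compartment: if the truth table plants
#' the variable present there, each of the cell's samples draws a
#' log-normal signal, independently zeroed with probability
#' \code{dropout}; otherwise the signal is zero.
#'
#' @param spec A [traffic_sim_spec()].
#' @return List with \code{table} ([abundance_table()]), \code{design}
#'   ([study_design()]) and \code{truth} (the planted truth table).
#' @export
generate_traffic_dataset <- function(spec) {
  stopifnot(inherits(spec, "traffic_sim_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  truth <- spec$truth
  phenos <- sort(unique(truth$phenotype))
  nodes <- spec$network$nodes
  vars <- unique(truth$variable)
  n <- spec$n_per_group

  design <- do.call(rbind, lapply(phenos, function(p)
    do.call(rbind, lapply(nodes, function(cm)
      data.frame(phenotype = p, compartment = cm,
                 sample_id = paste0(p, "_", gsub(" ", "_", cm), "_", seq_len(n)),
                 stringsAsFactors = FALSE)))))
  values <- matrix(0, nrow = nrow(design), ncol = length(vars),
                   dimnames = list(design$sample_id, vars))
  tkey <- paste(truth$variable, truth$phenotype)
  planted <- strsplit(truth$planted_compartments, ";", fixed = TRUE)
  names(planted) <- tkey
  for (v in vars) {
    for (p in phenos) {
      loc <- planted[[paste(v, p)]]
      if (is.null(loc)) next
      rows <- design$phenotype == p & design$compartment %in% loc
      k <- sum(rows)
      sig <- stats::rlnorm(k, spec$meanlog, spec$sdlog)
      if (spec$dropout > 0)
        sig[stats::runif(k) < spec$dropout] <- 0
      values[rows, v] <- sig
    }
  }
  list(table = abundance_table(design$sample_id, values),
       design = study_design(design$sample_id, design$phenotype,
                             design$compartment),
       truth = truth)
}

#' Simulation settings for a serum cohort
#'
#' Log-abundance of feature j for subject i:
#' baseline_j + sex_effect_j * [i is female] + bmi_slope_j * (BMI_i - 26)
#' + Normal(0, noise_sd). BMI is Normal per sex; the default means and SDs
#' (male 25.68 +/- 4.69, female 27.91 +/- 6.87 kg/m^2) mirror a large adult
#' serum cohort in which women average a higher BMI than men.
#'
#' @param n_male,n_female Subjects per sex (cohort-scale defaults 4176 and
#'   1105).
#' @param n_features Number of lipid features.
#' @param sex_effects Numeric vector (recycled) of additive female effects
#'   on the log scale.
#' @param bmi_slopes Numeric vector (recycled) of per-feature log-scale
#'   slopes on centred BMI.
#' @param bmi_mean_male,bmi_sd_male,bmi_mean_female,bmi_sd_female BMI model
#'   per sex (kg/m^2).
#' @param noise_sd Residual log-scale SD (> 0).
#' @param baseline Baseline log-abundance.
#' @param seed Integer seed.
#' @return A \code{cohort_sim_spec} list.
#' @export
cohort_sim_spec <- function(n_male = 4176L, n_female = 1105L,
                            n_features = 10L, sex_effects = 0,
                            bmi_slopes = 0,
                            bmi_mean_male = 25.68, bmi_sd_male = 4.69,
                            bmi_mean_female = 27.91, bmi_sd_female = 6.87,
                            noise_sd = 0.5, baseline = 5, seed = 1L) {
  if (noise_sd <= 0 || bmi_sd_male <= 0 || bmi_sd_female <= 0)
    stop("spreads must be > 0")
  if (any(!is.finite(c(sex_effects, bmi_slopes)))) stop("effects must be finite")
  structure(list(n_male = as.integer(n_male), n_female = as.integer(n_female),
                 n_features = as.integer(n_features),
                 sex_effects = rep_len(sex_effects, n_features),
                 bmi_slopes = rep_len(bmi_slopes, n_features),
                 bmi_mean_male = bmi_mean_male, bmi_sd_male = bmi_sd_male,
                 bmi_mean_female = bmi_mean_female, bmi_sd_female = bmi_sd_female,
                 noise_sd = noise_sd, baseline = baseline,
                 seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

#' Generate a serum cohort with known generative truth
#'
#' @param spec A [cohort_sim_spec()].
#' @return List with \code{cohort} (a [cohort_table()]; features on the raw
#'   abundance scale, i.e. exp of the log model) and \code{truth} (the
#'   spec, plus \code{bayes_auc}: the analytic optimal AUC when exactly one
#'   feature carries a pure sex effect with no BMI pathway, NA otherwise).
#' @details For a single feature with female-minus-male log-mean difference
#'   d and common residual SD s (no BMI slope), the optimal classifier is
#'   the feature itself and its AUC is Phi(d / (s * sqrt(2))) — the
#'   probability that a random female's value exceeds a random male's.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  n <- spec$n_male + spec$n_female
  sex <- c(rep("male", spec$n_male), rep("female", spec$n_female))
  bmi <- c(stats::rnorm(spec$n_male, spec$bmi_mean_male, spec$bmi_sd_male),
           stats::rnorm(spec$n_female, spec$bmi_mean_female, spec$bmi_sd_female))
  bmi <- pmax(bmi, 12)  # physiological floor
  age <- round(stats::rnorm(n, 54.3, 8.7))

  female <- as.numeric(sex == "female")
  feats <- matrix(NA_real_, n, spec$n_features)
  for (j in seq_len(spec$n_features)) {
    lg <- spec$baseline + spec$sex_effects[j] * female +
      spec$bmi_slopes[j] * (bmi - 26) + stats::rnorm(n, 0, spec$noise_sd)
    feats[, j] <- exp(lg)
  }
  colnames(feats) <- sprintf("PC(%d:%d)", 30 + seq_len(spec$n_features), 2L)

  active <- which(spec$sex_effects != 0)
  bayes_auc <- if (length(active) == 1L && all(spec$bmi_slopes == 0)) {
    stats::pnorm(abs(spec$sex_effects[active]) / (spec$noise_sd * sqrt(2)))
  } else NA_real_

  cohort <- cohort_table(data.frame(
    id = sprintf("s%05d", seq_len(n)), sex = sex, age = age, bmi = bmi,
    feats, check.names = FALSE, stringsAsFactors = FALSE))
  list(cohort = cohort, truth = c(unclass(spec), list(bayes_auc = bayes_auc)))
}
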