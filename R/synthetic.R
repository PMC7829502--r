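## Synthetic cohorts with planted time-varying community structure.
##
## Signal model: within each epoch, every module has one latent Gaussian
## driver per volume and a node's signal is
##   sqrt(rb) * global + sqrt(rw - rb) * driver(module) + sqrt(1 - rw) * noise
## (all unit-variance), so same-module pairs correlate at rw and
## different-module pairs at rb. Module memberships follow a switch
## schedule whose events are the ground truth for every downstream metric.

#' Planted dynamic-community design
#'
#' @param atlas an \code{atlas}; its networks are the initial modules.
#' @param n_epochs number of constant-membership epochs.
#' @param epoch_length volumes per epoch (>= 3; correlation is degenerate
#'   below that).
#' @param tr repetition time in seconds.
#' @param within_corr target Pearson correlation of same-module node
#'   pairs, in [0, 1).
#' @param between_corr target correlation of different-module pairs;
#'   must be below \code{within_corr} so the planted structure is
#'   detectable.
#' @param switch_schedule list of events, each a list with \code{epoch}
#'   (2..n_epochs; membership changes at the start of that epoch),
#'   \code{nodes}, \code{mode} ("disjoint": exactly 1 node; "cohesive":
#'   >= 2 nodes) and \code{to} (destination module index). Moves persist
#'   until a later event reassigns the node.
#' @param signal_sd overall scale of the series (arbitrary BOLD-like
#'   units).
#' @return a \code{planted_design}.
#' @export
planted_design <- function(atlas = synthetic_atlas(), n_epochs = 12L,
                           epoch_length = 20L, tr = 2.5,
                           within_corr = 0.6, between_corr = 0.1,
                           switch_schedule = list(), signal_sd = 1) {
  n_epochs <- as.integer(n_epochs); epoch_length <- as.integer(epoch_length)
  if (epoch_length < 3L)
    stop("epoch_length must be >= 3 volumes (correlation degenerate)")
  if (n_epochs < 2L) stop("need at least 2 epochs")
  if (within_corr <= between_corr)
    stop("within_corr must exceed between_corr (planted modularity)")
  if (within_corr >= 1 || within_corr < 0 || between_corr < 0)
    stop("correlations must satisfy 0 <= between < within < 1")
  n_modules <- nrow(atlas$networks)
  for (ev in switch_schedule) {
    stopifnot(all(c("epoch", "nodes", "mode", "to") %in% names(ev)))
    if (ev$epoch < 2L || ev$epoch > n_epochs)
      stop("event epoch must be in 2..n_epochs")
    if (any(ev$nodes < 1L) || any(ev$nodes > atlas$n_nodes))
      stop("event nodes out of range")
    if (ev$mode == "disjoint" && length(ev$nodes) != 1L)
      stop("a disjoint event moves exactly 1 node")
    if (ev$mode == "cohesive" && length(ev$nodes) < 2L)
      stop("a cohesive event moves >= 2 nodes")
    if (!ev$mode %in% c("disjoint", "cohesive"))
      stop("event mode must be 'disjoint' or 'cohesive'")
    if (ev$to < 1L || ev$to > n_modules)
      stop("event destination module out of range")
  }
  structure(list(atlas = atlas, n_nodes = atlas$n_nodes,
                 n_epochs = n_epochs, epoch_length = epoch_length,
                 n_volumes = n_epochs * epoch_length, tr = tr,
                 within_corr = within_corr, between_corr = between_corr,
                 switch_schedule = switch_schedule,
                 signal_sd = signal_sd), class = "planted_design")
}

#' Planted per-epoch module labels of a design
#' @param design a \code{planted_design}.
#' @return node x epoch integer matrix.
#' @export
planted_labels <- function(design) {
  labels <- matrix(rep(design$atlas$membership, design$n_epochs),
                   nrow = design$n_nodes)
  for (ev in design$switch_schedule)
    labels[ev$nodes, ev$epoch:design$n_epochs] <- ev$to
  labels
}

#' Generate one subject from a planted design
#'
#' Deterministic given the seed. The ground truth classifies each planted
#' membership change at each epoch boundary as disjoint or cohesive with
#' the same source-and-destination rule used by
#' \code{\link{change_events}}, so schedule collisions are resolved
#' consistently.
#'
#' @param design a \code{planted_design}.
#' @param seed integer seed.
#' @param subject_id,group,... passed through to
#'   \code{\link{subject_record}}.
#' @param motion simulate a slow realignment-parameter random walk
#'   (default TRUE).
#' @return list with \code{subject} (a \code{subject_record}) and
#'   \code{truth} (planted labels, events, per-node disjoint/cohesive
#'   counts).
#' @export
generate_subject <- function(design, seed, subject_id = "S1",
                             group = "unlabeled", motion = TRUE, ...) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  labels <- planted_labels(design)
  rw <- design$within_corr; rb <- design$between_corr
  a_g <- sqrt(rb); a_m <- sqrt(rw - rb); a_e <- sqrt(1 - rw)
  n <- design$n_nodes; L <- design$epoch_length
  ts <- matrix(0, n, design$n_volumes)
  for (e in seq_len(design$n_epochs)) {
    cols <- ((e - 1L) * L + 1L):(e * L)
    g <- rnorm(L)
    mods <- sort(unique(labels[, e]))
    drivers <- matrix(rnorm(length(mods) * L), length(mods), L)
    rownames(drivers) <- as.character(mods)
    eps <- matrix(rnorm(n * L), n, L)
    ts[, cols] <- design$signal_sd *
      (a_g * matrix(g, n, L, byrow = TRUE) +
       a_m * drivers[as.character(labels[, e]), , drop = FALSE] +
       a_e * eps)
  }
  mot <- NULL
  if (motion) {
    mot <- cbind(apply(matrix(rnorm(design$n_volumes * 3, sd = 0.01),
                              ncol = 3), 2L, cumsum),
                 apply(matrix(rnorm(design$n_volumes * 3, sd = 2e-4),
                              ncol = 3), 2L, cumsum))
  }
  ev <- change_events(labels)
  truth <- list(
    labels = labels, events = ev,
    disjoint_count = tabulate(ev$node[ev$kind == "disjoint"], nbins = n),
    cohesive_count = tabulate(ev$node[ev$kind == "cohesive"], nbins = n))
  list(subject = subject_record(subject_id, group, ts, motion = mot, ...),
       truth = truth)
}

#' Group-effect specification for synthetic cohorts
#'
#' Baseline switching applies to every subject: each node switches module
#' alone with probability \code{base_disjoint_p} per epoch boundary, and
#' with probability \code{base_cohesive_p} per boundary one group of 2-4
#' nodes from one network moves together. Subjects in the MHE-like group
#' additionally switch alone with probability \code{mhe_extra_disjoint_p}
#' at each boundary on the designated nodes (a subset of the
#' higher-cognitive DMN/FPN/VAN-like networks). Cognitive scores are tied
#' to the planted disjointness rate d (mean over the designated
#' networks' nodes):
#'   DST   = 62 - 0.45 age + 0.9 education - 120 d + N(0, 6)
#'   NCT-A = 25 + 0.35 age - 0.5 education + 160 d + N(0, 5)
#' so higher planted disjointness lowers DST and raises NCT-A.
#'
#' @param atlas the cohort's atlas.
#' @param base_disjoint_p,base_cohesive_p baseline event probabilities
#'   per epoch boundary.
#' @param mhe_extra_disjoint_p extra per-boundary disjoint-switch
#'   probability on designated nodes in the MHE-like group; 0 gives an
#'   exchangeable null cohort.
#' @param designated_networks network abbreviations carrying the effect.
#' @param n_designated number of designated nodes (spread over the
#'   designated networks).
#' @return a \code{cohort_effects} list.
#' @export
cohort_effects <- function(atlas = synthetic_atlas(),
                           base_disjoint_p = 0.04,
                           base_cohesive_p = 0.5,
                           mhe_extra_disjoint_p = 0.25,
                           designated_networks = c("DMN", "FPN", "VAN"),
                           n_designated = 10L) {
  keep <- atlas$networks$abbreviation %in% designated_networks
  if (!any(keep)) stop("no designated networks found in the atlas")
  pool_nets <- which(keep)
  # spread designated nodes over the designated networks, round-robin
  per <- split(rep(pool_nets, length.out = n_designated),
               rep(pool_nets, length.out = n_designated))
  designated <- sort(unlist(Map(function(net, cnt)
    atlas$networks$members[[net]][seq_len(cnt)],
    as.integer(names(per)), vapply(per, length, integer(1L)))))
  structure(list(
    base_disjoint_p = base_disjoint_p,
    base_cohesive_p = base_cohesive_p,
    mhe_extra_disjoint_p = mhe_extra_disjoint_p,
    designated_networks = designated_networks,
    designated_nodes = as.integer(designated),
    dst_beta = c(intercept = 62, age = -0.45, education = 0.9,
                 disjointness = -120), dst_sd = 6,
    nct_beta = c(intercept = 25, age = 0.35, education = -0.5,
                 disjointness = 160), nct_sd = 5), class = "cohort_effects")
}

# Random per-subject switch schedule under the effect specification.
random_schedule <- function(design, effects, is_mhe) {
  sched <- list()
  n_modules <- nrow(design$atlas$networks)
  for (e in 2:design$n_epochs) {
    p <- rep(effects$base_disjoint_p, design$n_nodes)
    if (is_mhe)
      p[effects$designated_nodes] <-
        p[effects$designated_nodes] + effects$mhe_extra_disjoint_p
    movers <- which(runif(design$n_nodes) < p)
    for (nd in movers) {
      sched[[length(sched) + 1L]] <- list(
        epoch = e, nodes = nd, mode = "disjoint",
        to = sample(setdiff(seq_len(n_modules),
                            design$atlas$membership[nd]), 1L))
    }
    if (runif(1L) < effects$base_cohesive_p) {
      net <- sample.int(n_modules, 1L)
      mem <- design$atlas$networks$members[[net]]
      size <- sample(2:min(4L, length(mem)), 1L)
      nodes <- sample(mem, size)
      sched[[length(sched) + 1L]] <- list(
        epoch = e, nodes = sort(nodes), mode = "cohesive",
        to = sample(setdiff(seq_len(n_modules), net), 1L))
    }
  }
  sched
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a full synthetic cohort
#'
#' Demographics are drawn per group to mirror a cirrhosis cohort (ages
#' around 48-51 years, ~12-13 years of education, majority male); blood
#' ammonia is drawn for the patient groups only. Reproducible from the
#' master seed via a per-subject counter scheme.
#'
#' @param n_per_group named counts, e.g. \code{c(HC = 41, noHE = 32,
#'   MHE = 30)}.
#' @param design a \code{planted_design}.
#' @param effects a \code{cohort_effects} (use
#'   \code{mhe_extra_disjoint_p = 0} for a null cohort).
#' @param seed master seed.
#' @return a \code{synthetic_cohort}: list with \code{subjects},
#'   \code{truth} (one ground-truth entry per subject), \code{design},
#'   \code{effects}, \code{groups}, \code{seed}.
#' @export
generate_cohort <- function(n_per_group = c(HC = 41L, noHE = 32L, MHE = 30L),
                            design = planted_design(),
                            effects = cohort_effects(design$atlas),
                            seed = 1L) {
  if (any(n_per_group < 1L) || length(n_per_group) == 0L)
    stop("every group must have at least one subject")
  groups <- rep(names(n_per_group), n_per_group)
  n_total <- length(groups)
  seeds <- derive_seeds(seed, 2L * n_total)
  demo <- list(HC  = list(age = c(50.1, 7.3), edu = c(13.0, 2.6), p_m = 28/41),
               noHE = list(age = c(47.9, 8.2), edu = c(12.3, 3.5), p_m = 18/32),
               MHE = list(age = c(50.9, 6.3), edu = c(12.3, 3.0), p_m = 21/30))
  subjects <- truths <- vector("list", n_total)
  nb <- design$n_epochs - 1L
  for (i in seq_len(n_total)) {
    g <- groups[i]
    d <- demo[[g]] %||% demo$HC
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    set.seed(seeds[i])
    age <- max(25, rnorm(1, d$age[1], d$age[2]))
    edu <- max(6, rnorm(1, d$edu[1], d$edu[2]))
    sex <- if (runif(1) < d$p_m) "M" else "F"
    sched <- random_schedule(design, effects, is_mhe = (g == "MHE"))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    des_i <- design
    des_i$switch_schedule <- sched
    gen <- generate_subject(des_i, seeds[n_total + i],
                            subject_id = sprintf("S%03d", i), group = g,
                            age = age, sex = sex, education = edu)
    # planted disjointness rate over the designated networks' nodes
    des_nets <- which(design$atlas$networks$abbreviation %in%
                        effects$designated_networks)
    des_members <- unlist(design$atlas$networks$members[des_nets])
    dval <- mean(gen$truth$disjoint_count[des_members] / nb)
    set.seed(seeds[i] + 1L)
    dst <- effects$dst_beta["intercept"] + effects$dst_beta["age"] * age +
      effects$dst_beta["education"] * edu +
      effects$dst_beta["disjointness"] * dval + rnorm(1, 0, effects$dst_sd)
    nct <- effects$nct_beta["intercept"] + effects$nct_beta["age"] * age +
      effects$nct_beta["education"] * edu +
      effects$nct_beta["disjointness"] * dval + rnorm(1, 0, effects$nct_sd)
    ammonia <- if (g == "noHE") max(5, rnorm(1, 55.1, 21.3))
               else if (g == "MHE") max(5, rnorm(1, 72.6, 31.5))
               else NA_real_
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    s <- gen$subject
    s$dst <- unname(dst); s$nct_a <- unname(nct)
    s$blood_ammonia <- ammonia
    subjects[[i]] <- s
    gen$truth$planted_disjointness_designated <- dval
    truths[[i]] <- gen$truth
  }
  structure(list(subjects = subjects, truth = truths, groups = groups,
                 design = design, effects = effects,
                 seed = as.integer(seed)), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%s), %d nodes x %d volumes\n",
              length(x$subjects),
              paste(sprintf("%s=%d", names(table(x$groups)),
                            table(x$groups)), collapse = ", "),
              x$design$n_nodes, x$design$n_volumes))
  invisible(x)
}
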