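# Synthetic two-group communities: a shared abundant compositional
# background plus a handful of planted low-abundance marker taxa whose close
# phylogenetic relatives may carry the mass in the opposite group. This is
# the scenario in which whole-community distances are blind to the group
# signal while the marker-restricted local distance is not, and it drives
# every end-to-end test in the package.

#' Scenario configuration for the synthetic generator
#'
#' Defaults encode the two-group artificial study: 100 samples (50 per
#' group), a shared abundant background, and 4 group-differential
#' low-abundance markers, each paired with a sibling "relative" leaf on a
#' short cherry. Marker abundances are log-normal around
#' `marker_mean_abundance` with a `marker_effect` fold-change between groups
#' and `marker_sdlog` within-group noise; with probability
#' `relative_presence` a marker is absent from its low group and its
#' relative carries comparable mass in both groups instead (so the relative
#' itself is not group-differential). Background compositions are Dirichlet
#' draws with concentration `background_concentration` around one shared
#' base profile, identical in distribution for both groups.
#'
#' @param n_per_group samples per group (default 50).
#' @param n_background shared abundant background taxa (default 30).
#' @param n_markers planted group-differential markers (default 4); 0 gives
#'   the exchangeable null scenario.
#' @param marker_mean_abundance mean marker fraction in the enriched group
#'   (default 0.005).
#' @param marker_effect fold-change by which a marker is depleted in its low
#'   group (default 8): group A carries mean fraction
#'   `marker_mean_abundance`, group B `marker_mean_abundance / marker_effect`.
#' @param marker_sdlog log-scale SD of marker abundances within a group
#'   (default 0.45).
#' @param marker_detect_prob probability that a marker (or relative) that
#'   should be present in a sample is actually observed (default 0.9);
#'   models the profiling sparsity under which samples share few exact
#'   markers.
#' @param relative_presence probability that a marker is replaced in its low
#'   group by its sibling relative (default 0.75).
#' @param background_concentration Dirichlet concentration of the background
#'   (larger = less compositional noise; default 40).
#' @param branch_scale multiplier on all generated branch lengths
#'   (default 1).
#' @param t_s,d_f thresholds recorded in the generated neighbor index
#'   (defaults 0.92 / 0.11, the reference-database values).
#' @param seed integer RNG seed (default 1).
#' @return list of class `fms_scenario`.
#' @export
scenario_config <- function(n_per_group = 50L, n_background = 30L, n_markers = 4L,
                            marker_mean_abundance = 0.005, marker_effect = 8,
                            marker_sdlog = 0.45, marker_detect_prob = 0.9,
                            relative_presence = 0.75,
                            background_concentration = 40, branch_scale = 1,
                            t_s = 0.92, d_f = 0.11, seed = 1L) {
  cfg <- list(
    n_per_group = as.integer(n_per_group), n_background = as.integer(n_background),
    n_markers = as.integer(n_markers),
    marker_mean_abundance = marker_mean_abundance, marker_effect = marker_effect,
    marker_sdlog = marker_sdlog, marker_detect_prob = marker_detect_prob,
    relative_presence = relative_presence,
    background_concentration = background_concentration, branch_scale = branch_scale,
    t_s = t_s, d_f = d_f, seed = as.integer(seed)
  )
  if (cfg$n_per_group < 1L || cfg$n_background < 1L || cfg$n_markers < 0L) {
    fms_validation_stop("counts must be positive (n_markers may be 0)")
  }
  if (cfg$marker_mean_abundance <= 0 || cfg$marker_mean_abundance >= 1) {
    fms_validation_stop("marker_mean_abundance must lie in (0, 1)")
  }
  if (cfg$relative_presence < 0 || cfg$relative_presence > 1) {
    fms_validation_stop("relative_presence must lie in [0, 1]")
  }
  if (cfg$marker_detect_prob <= 0 || cfg$marker_detect_prob > 1) {
    fms_validation_stop("marker_detect_prob must lie in (0, 1]")
  }
  if (cfg$marker_effect < 1) fms_validation_stop("marker_effect must be >= 1")
  if (cfg$background_concentration <= 0 || cfg$branch_scale <= 0) {
    fms_validation_stop("concentration and branch_scale must be positive")
  }
  # premise of the scenario: marker mass is a small fraction of the community
  if (cfg$n_markers * cfg$marker_mean_abundance * cfg$marker_effect > 0.2) {
    fms_validation_stop("marker mass must remain small relative to the background")
  }
  structure(cfg, class = "fms_scenario")
}

# ladder Newick over pre-rendered unit strings with given stem lengths
.ladder_newick <- function(units, stems, inner) {
  s <- sprintf("(%s:%.6f,%s:%.6f)", units[1L], stems[1L], units[2L], stems[2L])
  if (length(units) > 2L) {
    for (k in seq(3L, length(units))) {
      s <- sprintf("(%s:%.6f,%s:%.6f)", s, inner[k - 2L], units[k], stems[k])
    }
  }
  paste0(s, ";")
}

#' Simulate a two-group community dataset
#'
#' Generates every artifact a full analysis needs: feature table (columns
#' renormalized to 1), rooted tree with marker-relative cherries, taxonomy
#' (identical lineages within a cherry), function profiles (near-identical
#' within a cherry) with a KO hierarchy, a neighbor index listing each
#' cherry pair with similarity above `t_s`, sample metadata, and the
#' planted-truth record used by tests. Fully reproducible from the seed.
#'
#' @param cfg an `fms_scenario` from [scenario_config()].
#' @param seed optional override of `cfg$seed`.
#' @return list of class `fms_dataset` with elements `table`, `tree`,
#'   `taxonomy`, `profiles`, `hierarchy`, `index`, `metadata`, `truth`,
#'   `config`.
#' @examples
#' ds <- simulate_dataset(scenario_config(n_per_group = 5, seed = 7))
#' dim(ds$table)
#' @export
simulate_dataset <- function(cfg = scenario_config(), seed = NULL) {
  if (!inherits(cfg, "fms_scenario")) fms_validation_stop("cfg must come from scenario_config()")
  set.seed(seed %||% cfg$seed)
  nb <- cfg$n_background
  nm <- cfg$n_markers
  n <- 2L * cfg$n_per_group
  bg_ids <- sprintf("bg_%02d", seq_len(nb))
  mk_ids <- if (nm > 0L) sprintf("mk_%02d", seq_len(nm)) else character()
  rel_ids <- if (nm > 0L) sprintf("rel_%02d", seq_len(nm)) else character()
  samples <- c(
    sprintf("A%03d", seq_len(cfg$n_per_group)),
    sprintf("B%03d", seq_len(cfg$n_per_group))
  )
  group <- rep(c("A", "B"), each = cfg$n_per_group)

  # planted marker design: markers enriched in group A, per-marker replacement
  high <- rep("A", nm)
  replaced <- if (nm > 0L) stats::runif(nm) < cfg$relative_presence else logical()
  mu_hi <- cfg$marker_mean_abundance
  mu_lo <- cfg$marker_mean_abundance / cfg$marker_effect
  # log-normal with arithmetic mean mu, then sparsity dropout
  ln <- function(k, mu) stats::rlnorm(k, log(mu) - cfg$marker_sdlog^2 / 2, cfg$marker_sdlog)
  detect <- function(k) as.numeric(stats::runif(k) < cfg$marker_detect_prob)

  marker_abd <- matrix(0, nm, n, dimnames = list(mk_ids, samples))
  rel_abd <- matrix(0, nm, n, dimnames = list(rel_ids, samples))
  if (nm > 0L) {
    for (j in seq_len(nm)) {
      hi <- group == high[j]
      marker_abd[j, hi] <- ln(sum(hi), mu_hi) * detect(sum(hi))
      if (replaced[j]) {
        # marker absent from its low group; the relative carries comparable
        # mass in BOTH groups, so the relative itself is not differential
        rel_abd[j, ] <- ln(n, mu_hi) * detect(n)
      } else {
        marker_abd[j, !hi] <- ln(sum(!hi), mu_lo) * detect(sum(!hi))
      }
    }
  }

  # shared compositional background, same distribution in both groups
  base <- sort(stats::rlnorm(nb, 0, 1), decreasing = TRUE)
  base <- base / sum(base)
  bg_raw <- matrix(
    stats::rgamma(nb * n, shape = rep(cfg$background_concentration * base, n), rate = 1),
    nb, n, dimnames = list(bg_ids, samples)
  )
  bg_frac <- sweep(bg_raw, 2L, colSums(bg_raw), "/")
  special_mass <- colSums(marker_abd) + colSums(rel_abd)
  if (any(special_mass >= 0.9)) fms_stop("planted marker mass exploded; lower marker parameters")
  table <- rbind(
    sweep(bg_frac, 2L, 1 - special_mass, "*"),
    marker_abd, rel_abd
  )
  table <- validate_feature_table(table)

  # tree: each marker-relative pair sits on a short cherry; background taxa
  # and cherries are laddered in random order
  unit_ids <- c(bg_ids, if (nm > 0L) sprintf("cherry_%02d", seq_len(nm)))
  ord <- sample(length(unit_ids))
  cherry_leaf_d <- matrix(stats::runif(2L * max(nm, 1L), 0.05, 0.15) * cfg$branch_scale, ncol = 2L)
  units <- vapply(unit_ids, function(u) {
    if (startsWith(u, "bg_")) {
      u
    } else {
      j <- as.integer(sub("cherry_", "", u))
      sprintf("(%s:%.6f,%s:%.6f)", mk_ids[j], cherry_leaf_d[j, 1L], rel_ids[j], cherry_leaf_d[j, 2L])
    }
  }, character(1L))[ord]
  nu <- length(units)
  stems <- stats::runif(nu, 0.2, 0.8) * cfg$branch_scale
  inner <- stats::runif(max(nu - 2L, 1L), 0.1, 0.3) * cfg$branch_scale
  tree <- validate_tree(ape::read.tree(text = .ladder_newick(units, stems, inner)))

  # taxonomy: cherry members share the full lineage; background taxa are
  # each their own genus
  lineage <- function(ph, gen) {
    sprintf("k__Bacteria;p__P%02d;c__C01;o__O01;f__F01;g__%s;s__", ph, gen)
  }
  taxonomy <- c(
    stats::setNames(lineage(seq_len(nb) %% 5L + 1L, sprintf("Gbg%02d", seq_len(nb))), bg_ids),
    if (nm > 0L) stats::setNames(rep(lineage(6L, sprintf("Gmk%02d", seq_len(nm))), 2L),
                                 c(mk_ids, rel_ids))
  )

  # function profiles: 30 KOs in a 3-level hierarchy; cherry pairs
  # near-identical, everything else independent
  kos <- sprintf("ko%03d", seq_len(30L))
  hierarchy <- data.frame(
    ko = kos,
    level2 = sprintf("L2_%02d", (seq_along(kos) - 1L) %/% 3L + 1L),
    level1 = sprintf("L1_%02d", (seq_along(kos) - 1L) %/% 8L + 1L),
    stringsAsFactors = FALSE
  )
  all_ids <- c(bg_ids, mk_ids, rel_ids)
  profiles <- matrix(stats::rgamma(length(all_ids) * length(kos), 1, 1),
    length(all_ids), length(kos), dimnames = list(all_ids, kos)
  )
  if (nm > 0L) {
    noise <- matrix(stats::runif(nm * length(kos), 0.95, 1.05), nm, length(kos))
    profiles[rel_ids, ] <- profiles[mk_ids, , drop = FALSE] * noise
  }

  # neighbor index: each cherry pair, both directions, similarity >= t_s
  sim <- if (nm > 0L) stats::runif(nm, cfg$t_s + 0.01, 0.98) else numeric()
  neighbors <- if (nm > 0L) {
    data.frame(
      feature = c(mk_ids, rel_ids), neighbor = c(rel_ids, mk_ids),
      similarity = rep(sim, 2L), stringsAsFactors = FALSE
    )
  } else {
    data.frame(feature = character(), neighbor = character(), similarity = numeric())
  }
  index <- new_neighbor_index(cfg$t_s, cfg$d_f, neighbors)

  metadata <- data.frame(group = group, row.names = samples, stringsAsFactors = FALSE)
  truth <- data.frame(
    marker = mk_ids, relative = rel_ids, high_group = high,
    replaced = replaced, similarity = sim, stringsAsFactors = FALSE
  )
  structure(
    list(
      table = table, tree = tree, taxonomy = taxonomy, profiles = profiles,
      hierarchy = hierarchy, index = index, metadata = metadata,
      truth = truth, config = cfg
    ),
    class = "fms_dataset"
  )
}

#' @export
print.fms_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic dataset: %d taxa x %d samples (%d background, %d planted marker(s))\n",
    nrow(x$table), ncol(x$table), x$config$n_background, x$config$n_markers
  ))
  invisible(x)
}

#' Write a simulated dataset as a plain-text fixture bundle
#'
#' Writes the eight artifacts (`table.tsv`, `tree.nwk`, `taxonomy.tsv`,
#' `functions.tsv`, `ko_hierarchy.tsv`, `index.tsv`, `metadata.tsv`,
#' `truth.tsv`) in the package's text dialects with fixed decimal
#' formatting, so regenerating from the same seed reproduces the files
#' byte-for-byte.
#'
#' @param dataset an `fms_dataset` from [simulate_dataset()].
#' @param outdir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_fixture_bundle <- function(dataset, outdir) {
  if (!inherits(dataset, "fms_dataset")) fms_validation_stop("dataset must come from simulate_dataset()")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  num_tsv <- function(m, id_col, path, digits = 8L) {
    fmt <- paste0("%.", digits, "f")
    lines <- c(
      paste(c(id_col, colnames(m)), collapse = "\t"),
      vapply(seq_len(nrow(m)), function(i) {
        paste(c(rownames(m)[i], sprintf(fmt, m[i, ])), collapse = "\t")
      }, character(1L))
    )
    writeLines(lines, path, sep = "\n")
  }
  num_tsv(dataset$table, "#OTU ID", p("table.tsv"))
  ape::write.tree(dataset$tree, p("tree.nwk"))
  writeLines(sprintf("%s\t%s", names(dataset$taxonomy), dataset$taxonomy), p("taxonomy.tsv"))
  num_tsv(dataset$profiles, "feature_id", p("functions.tsv"), digits = 6L)
  writeLines(
    c("ko\tlevel2\tlevel1", sprintf(
      "%s\t%s\t%s",
      dataset$hierarchy$ko, dataset$hierarchy$level2, dataset$hierarchy$level1
    )),
    p("ko_hierarchy.tsv")
  )
  write_neighbor_index(dataset$index, p("index.tsv"))
  writeLines(
    c("sample\tgroup", sprintf("%s\t%s", rownames(dataset$metadata), dataset$metadata$group)),
    p("metadata.tsv")
  )
  writeLines(
    c(
      "marker\trelative\thigh_group\treplaced\tsimilarity",
      if (nrow(dataset$truth) > 0L) {
        sprintf(
          "%s\t%s\t%s\t%s\t%.6f",
          dataset$truth$marker, dataset$truth$relative, dataset$truth$high_group,
          dataset$truth$replaced, dataset$truth$similarity
        )
      }
    ),
    p("truth.tsv")
  )
  invisible(file.path(outdir, c(
    "table.tsv", "tree.nwk", "taxonomy.tsv", "functions.tsv",
    "ko_hierarchy.tsv", "index.tsv", "metadata.tsv", "truth.tsv"
  )))
}
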