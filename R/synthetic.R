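#' Synthetic immunopeptidome generator configuration
#'
#' Bundles every knob of the seeded generators with defaults that emulate the
#' statistical structure of class I immunopeptidome cohorts: 9-mer-dominated
#' length distribution (70% 9-mers), three technical replicates with ~0.8
#' per-replicate detection probability, ~5% proteolytic ladder artifacts, and
#' exact-count planting of tumor-exclusive peptides.
#'
#' @param seed RNG seed; identical configs yield identical outputs.
#' @param n_proteins,protein_length proteome size and per-protein length range.
#' @param pwms allotype motif set, shared with [pwm_predictor()].
#' @param hla_class `"I"` or `"II"`.
#' @param length_weights named numeric: peptide length -> sampling weight.
#' @param n_ligands ligand peptides per sample.
#' @param artifact_fraction fraction of a sample's peptides that are planted
#'   ladder artifacts.
#' @param ladder_min_fragments,ladder_step_max,hotspot_length ladder geometry:
#'   at least this many overlapping fragments, successive start offsets at
#'   most `ladder_step_max`, within a degradation hotspot of this length.
#' @param fragment_length artifact fragment length range.
#' @param replicates,p_detect technical replicates per sample and
#'   per-replicate detection probability (every assigned peptide is detected
#'   in at least one replicate, so the sample union is exactly the assigned
#'   set).
#' @param n_benign,n_tumor cohort sizes for [gen_cohorts()].
#' @param n_housekeeping size of the shared benign/tumor peptide pool.
#' @param housekeeping_p per-sample inclusion probability of a housekeeping
#'   peptide (each is forced into at least one benign sample).
#' @param planted_exclusives data.frame with columns `frequency` and
#'   `allotype` (`NA` = unrestricted): one planted tumor-exclusive peptide per
#'   row, present in exactly `round(frequency * n)` of the eligible tumor
#'   samples.
#' @param label_delta isotope label mass shift (Da) for synthetic spectra
#'   (+6.02013 emulates a 13C6 residue).
#' @param spectrum_noise_sd multiplicative (log-normal) intensity noise.
#' @param noise_peaks expected number of random noise peaks per spectrum.
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_proteins = 400L,
                             protein_length = c(300L, 600L),
                             pwms = default_pwms(),
                             hla_class = "I",
                             length_weights = NULL,
                             n_ligands = 380L,
                             artifact_fraction = 0.05,
                             ladder_min_fragments = 4L,
                             ladder_step_max = 3L,
                             hotspot_length = 40L,
                             fragment_length = c(8L, 16L),
                             replicates = 3L,
                             p_detect = 0.8,
                             n_benign = 10L,
                             n_tumor = 20L,
                             n_housekeeping = 400L,
                             housekeeping_p = 0.7,
                             planted_exclusives = default_plants(),
                             label_delta = 6.02013,
                             spectrum_noise_sd = 0.25,
                             noise_peaks = 10) {
  if (is.null(length_weights)) {
    length_weights <- if (hla_class == "I") {
      c("8" = 0.10, "9" = 0.70, "10" = 0.14, "11" = 0.06)
    } else {
      stats::setNames(rep(1 / 7, 7), as.character(12:18))
    }
  }
  cfg <- list(seed = as.integer(seed), n_proteins = n_proteins,
              protein_length = protein_length, pwms = pwms,
              hla_class = hla_class, length_weights = length_weights,
              n_ligands = n_ligands, artifact_fraction = artifact_fraction,
              ladder_min_fragments = ladder_min_fragments,
              ladder_step_max = ladder_step_max,
              hotspot_length = hotspot_length,
              fragment_length = fragment_length,
              replicates = as.integer(replicates), p_detect = p_detect,
              n_benign = n_benign, n_tumor = n_tumor,
              n_housekeeping = n_housekeeping, housekeeping_p = housekeeping_p,
              planted_exclusives = planted_exclusives,
              label_delta = label_delta,
              spectrum_noise_sd = spectrum_noise_sd, noise_peaks = noise_peaks)
  stopifnot(cfg$p_detect > 0, cfg$p_detect <= 1,
            cfg$artifact_fraction >= 0, cfg$artifact_fraction < 1,
            cfg$housekeeping_p > 0, cfg$housekeeping_p <= 1)
  class(cfg) <- "generator_config"
  cfg
}

#' Default planted tumor-exclusive peptides
#'
#' Frequencies span the display (0.05) and broad-presentation (0.20)
#' boundaries plus mid-range and universal plants; two plants are restricted
#' to an allotype-matched sub-cohort.
#'
#' @return data.frame with `frequency` and `allotype` columns.
#' @export
default_plants <- function() {
  data.frame(
    frequency = c(0.05, 0.15, 0.20, 0.25, 0.50, 1.00, 0.50, 1.00),
    allotype = c(NA, NA, NA, NA, NA, NA, "A*02", "B*07"),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic proteome
#'
#' Residues drawn i.i.d. from the package background composition.
#'
#' @param config a [generator_config()] (its seed is applied).
#' @return named character vector (accessions `SYNP0001`, ...).
#' @export
gen_proteome <- function(config) {
  set.seed(config$seed)
  lens <- sample(config$protein_length[1]:config$protein_length[2],
                 config$n_proteins, replace = TRUE)
  out <- vapply(lens, function(L) {
    paste(sample(AA_ALPHABET, L, replace = TRUE, prob = AA_BACKGROUND),
          collapse = "")
  }, character(1))
  names(out) <- sprintf("SYNP%04d", seq_along(out))
  out
}

# sample a peptide length from the configured weights
sample_length <- function(config) {
  as.integer(sample(names(config$length_weights), 1L,
                    prob = config$length_weights))
}

# Plant n motif-consistent ligand windows into the proteome at non-overlapping
# positions. Each window is overwritten with a draw from its allotype PWM, so
# ligands are exact proteome substrings. Returns the modified proteome plus a
# window table.
plant_ligand_windows <- function(proteome, config, n, occupied = NULL) {
  if (is.null(occupied)) {
    occupied <- lapply(proteome, function(s) logical(nchar(s)))
  }
  allotypes <- names(config$pwms)
  rows <- vector("list", n)
  # cycle proteins in shuffled order so windows spread evenly over the
  # proteome (keeps per-protein ligand coverage narrow)
  acc_cycle <- sample(rep(names(proteome), length.out = max(n, length(proteome))))
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in 1:200) {
      len <- sample_length(config)
      acc <- if (try == 1L) acc_cycle[1L + (i - 1L) %% length(acc_cycle)] else
        sample(names(proteome), 1L)
      L <- nchar(proteome[[acc]])
      if (L < len + 2L) next
      start <- sample.int(L - len + 1L, 1L)
      span <- start:(start + len - 1L)
      if (any(occupied[[acc]][span])) next
      allo <- sample(allotypes, 1L)
      pep <- pwm_sample(config$pwms[[allo]], len)
      substr(proteome[[acc]], start, start + len - 1L) <- pep
      occupied[[acc]][span] <- TRUE
      rows[[i]] <- tibble::tibble(sequence = pep, accession = acc,
                                  start = start, end = start + len - 1L,
                                  allotype = allo)
      placed <- TRUE
      break
    }
    if (!placed) stop("proteome too crowded to plant ligand windows",
                      call. = FALSE)
  }
  list(proteome = proteome, windows = do.call(rbind, rows),
       occupied = occupied)
}

# Draw one proteolytic ladder: >= min_fragments overlapping fragments whose
# successive starts differ by at most step_max, inside a hotspot window.
gen_ladder <- function(proteome, config, n_fragments, accession = NULL) {
  n_fragments <- max(n_fragments, config$ladder_min_fragments)
  repeat {
    acc <- accession %||% sample(names(proteome), 1L)
    L <- nchar(proteome[[acc]])
    if (L <= config$hotspot_length + 2L) {
      if (!is.null(accession)) stop("hotspot longer than protein ", acc,
                                    call. = FALSE)
      next
    }
    h_start <- sample.int(L - config$hotspot_length, 1L)
    h_end <- h_start + config$hotspot_length - 1L
    starts <- h_start + cumsum(c(0L, sample.int(config$ladder_step_max,
                                                n_fragments - 1L,
                                                replace = TRUE)))
    lens <- sample(config$fragment_length[1]:config$fragment_length[2],
                   n_fragments, replace = TRUE)
    ends <- pmin(starts + lens - 1L, h_end)
    keep <- ends - starts + 1L >= config$fragment_length[1]
    if (sum(keep) < config$ladder_min_fragments) next
    starts <- starts[keep]; ends <- ends[keep]
    return(tibble::tibble(
      sequence = substring(proteome[[acc]], starts, ends),
      accession = acc, start = starts, end = ends))
  }
}

# detection pattern over R replicates, conditioned on at least one detection
detect_pattern <- function(R, p) {
  repeat {
    pat <- stats::runif(R) < p
    if (any(pat)) return(pat)
  }
}

# assemble a pep_sample from an assigned peptide table with columns
# sequence/accession (proteins) by splitting into replicate detections
assemble_sample <- function(assigned, sample_id, donor_id, tissue,
                            cohort_label, hla_class, hla_typing, config) {
  R <- config$replicates
  reps <- lapply(seq_len(R), function(k) k)
  det <- t(vapply(seq_len(nrow(assigned)),
                  function(i) detect_pattern(R, config$p_detect),
                  logical(R)))
  reps <- lapply(seq_len(R), function(k) {
    tab <- assigned[det[, k], , drop = FALSE]
    tibble::tibble(sequence = tab$sequence, proteins = tab$accession,
                   modifications = NA_character_,
                   area = round(stats::rlnorm(nrow(tab), 10, 1), 3),
                   quality = round(stats::runif(nrow(tab), 20, 60), 2),
                   binder = tab$binder)
  })
  names(reps) <- sprintf("R%d", seq_len(R))
  pep_sample(sample_id, donor_id, tissue, cohort_label, hla_class,
             hla_typing, reps)
}

#' Generate a proteolysis study cohort with planted ladder artifacts
#'
#' Builds a proteome with planted motif ligands, then a cohort in which each
#' sample carries `n_ligands` allotype-matched ligands plus planted
#' proteolytic ladder artifacts making up `artifact_fraction` of its
#' peptides. Ground truth records every peptide's label.
#'
#' @param config a [generator_config()].
#' @param n_samples number of samples.
#' @return list with `proteome`, `cohort` (a [pep_cohort()]) and `truth`
#'   (per-sample tibbles with `sequence`, `label` in ligand/artifact).
#' @export
gen_proteolysis_cohort <- function(config, n_samples = 10L) {
  proteome <- gen_proteome(config)  # seeds the stream
  pool_size <- config$n_ligands * 3L
  planted <- plant_ligand_windows(proteome, config, pool_size)
  proteome <- planted$proteome
  pool <- planted$windows
  # re-extract in case of any residual mismatch (defensive; plants are disjoint)
  pool$sequence <- substring(proteome[pool$accession], pool$start, pool$end)

  allotypes <- names(config$pwms)
  samples <- vector("list", n_samples)
  truth <- vector("list", n_samples)
  n_art <- if (config$artifact_fraction > 0) {
    max(config$ladder_min_fragments,
        round(config$artifact_fraction * config$n_ligands /
                (1 - config$artifact_fraction)))
  } else 0L
  # degradation targets: the shortest quartile of proteins, so the ladder
  # hotspots cover a visible fraction of their source protein
  lens <- nchar(proteome)
  short_accs <- names(proteome)[lens <= stats::quantile(lens, 0.25)]
  for (s in seq_len(n_samples)) {
    typing <- sample(allotypes, 2L)
    eligible <- pool[pool$allotype %in% typing, , drop = FALSE]
    take <- eligible[sample.int(nrow(eligible),
                                min(config$n_ligands, nrow(eligible))), ,
                     drop = FALSE]
    ligands <- tibble::tibble(sequence = take$sequence,
                              accession = take$accession,
                              binder = paste0(take$allotype, "=strong"))
    # all of a sample's ladders degrade one protein, at distinct hotspots
    arts <- NULL
    if (n_art > 0L) {
      degraded <- sample(short_accs, 1L)
      ladder_sizes <- rep(config$ladder_min_fragments + 2L,
                          n_art %/% (config$ladder_min_fragments + 2L))
      rem <- n_art - sum(ladder_sizes)
      if (rem >= config$ladder_min_fragments) {
        ladder_sizes <- c(ladder_sizes, rem)
      } else if (rem > 0L && length(ladder_sizes) > 0L) {
        ladder_sizes[length(ladder_sizes)] <- ladder_sizes[length(ladder_sizes)] + rem
      } else if (length(ladder_sizes) == 0L) {
        ladder_sizes <- n_art
      }
      arts <- do.call(rbind, lapply(ladder_sizes, function(k) {
        gen_ladder(proteome, config, k, accession = degraded)
      }))
    }
    artifacts <- if (is.null(arts)) {
      tibble::tibble(sequence = character(0), accession = character(0),
                     binder = character(0))
    } else {
      tibble::tibble(sequence = arts$sequence, accession = arts$accession,
                     binder = NA_character_)
    }
    assigned <- rbind(ligands, artifacts)
    assigned <- assigned[!duplicated(assigned$sequence), , drop = FALSE]
    sid <- sprintf("S%02d", s)
    samples[[s]] <- assemble_sample(assigned, sid, paste0("D", s), "PBMC",
                                    "benign", config$hla_class, typing, config)
    truth[[s]] <- tibble::tibble(
      sequence = assigned$sequence,
      label = ifelse(assigned$sequence %in% artifacts$sequence,
                     "artifact", "ligand"))
    names(truth)[s] <- sid
  }
  list(proteome = proteome,
       cohort = pep_cohort("proteolysis_study", samples),
       truth = truth)
}

#' Generate benign and tumor cohorts with planted exclusives
#'
#' Both cohorts share a housekeeping peptide pool (every housekeeping peptide
#' is guaranteed to occur in at least one benign sample); tumor samples
#' additionally carry the planted tumor-exclusive peptides, each present in
#' exactly `round(frequency * n)` eligible samples (all tumor samples, or the
#' allotype-matched ones for restricted plants) and in no benign sample.
#'
#' @param config a [generator_config()].
#' @return list with `proteome`, `benign` and `tumor` ([pep_cohort()]s) and
#'   `truth`: `planted` (tibble with `peptide`, `frequency`, `allotype`,
#'   `n_positive`, `samples`), `housekeeping` (identity vector) and any
#'   rounding `warnings`.
#' @export
gen_cohorts <- function(config) {
  proteome <- gen_proteome(config)
  n_plants <- nrow(config$planted_exclusives)
  planted_hk <- plant_ligand_windows(proteome, config, config$n_housekeeping)
  planted_ex <- plant_ligand_windows(planted_hk$proteome, config, n_plants,
                                     occupied = planted_hk$occupied)
  proteome <- planted_ex$proteome
  hk <- planted_hk$windows
  hk$sequence <- substring(proteome[hk$accession], hk$start, hk$end)
  ex <- planted_ex$windows
  ex$sequence <- substring(proteome[ex$accession], ex$start, ex$end)

  allotypes <- names(config$pwms)
  # sample typings; make sure every allotype has carriers in the tumor cohort
  typing_for <- function(n) {
    t <- lapply(seq_len(n), function(i) sample(allotypes, 2L))
    for (a in allotypes) {
      if (!any(vapply(t, function(x) a %in% x, logical(1)))) {
        i <- sample.int(n, 1L)
        t[[i]] <- c(a, sample(setdiff(allotypes, a), 1L))
      }
    }
    t
  }
  benign_typing <- typing_for(config$n_benign)
  tumor_typing <- typing_for(config$n_tumor)

  # housekeeping membership: Bernoulli, forced into >= 1 benign sample
  hk_in_benign <- matrix(stats::runif(config$n_housekeeping * config$n_benign) <
                           config$housekeeping_p,
                         nrow = config$n_housekeeping)
  none <- which(rowSums(hk_in_benign) == 0L)
  for (i in none) hk_in_benign[i, sample.int(config$n_benign, 1L)] <- TRUE
  hk_in_tumor <- matrix(stats::runif(config$n_housekeeping * config$n_tumor) <
                          config$housekeeping_p,
                        nrow = config$n_housekeeping)

  # planted exclusives: exact-count membership among eligible tumor samples
  plants <- config$planted_exclusives
  plant_rows <- vector("list", n_plants)
  warnings <- character(0)
  plant_members <- matrix(FALSE, nrow = n_plants, ncol = config$n_tumor)
  for (i in seq_len(n_plants)) {
    allo <- plants$allotype[i]
    eligible <- if (is.na(allo)) seq_len(config$n_tumor) else
      which(vapply(tumor_typing, function(x) allo %in% x, logical(1)))
    # restricted plants must fit the allotype's motif so the restriction is
    # biologically coherent; resample the window's peptide from that PWM
    if (!is.na(allo) && ex$allotype[i] != allo) {
      len <- ex$end[i] - ex$start[i] + 1L
      pep <- pwm_sample(config$pwms[[allo]], len)
      substr(proteome[[ex$accession[i]]], ex$start[i], ex$end[i]) <- pep
      ex$sequence[i] <- pep
      ex$allotype[i] <- allo
    }
    k <- round(plants$frequency[i] * length(eligible))
    if (abs(k - plants$frequency[i] * length(eligible)) > 1e-9) {
      warnings <- c(warnings, sprintf(
        "plant %d: frequency %.3f x %d samples rounded to %d",
        i, plants$frequency[i], length(eligible), k))
    }
    members <- sort(sample(eligible, k))
    plant_members[i, members] <- TRUE
    plant_rows[[i]] <- tibble::tibble(
      peptide = ex$sequence[i], frequency = k / length(eligible),
      allotype = allo, n_positive = k, n_eligible = length(eligible),
      samples = list(sprintf("T%02d", members)))
  }

  build_cohort <- function(role, n, typing, hk_member, plant_member = NULL) {
    samples <- vector("list", n)
    for (s in seq_len(n)) {
      idx <- which(hk_member[, s])
      take <- hk[idx, , drop = FALSE]
      assigned <- tibble::tibble(sequence = take$sequence,
                                 accession = take$accession,
                                 binder = paste0(take$allotype, "=strong"))
      if (!is.null(plant_member)) {
        pidx <- which(plant_member[, s])
        if (length(pidx) > 0L) {
          assigned <- rbind(assigned, tibble::tibble(
            sequence = ex$sequence[pidx], accession = ex$accession[pidx],
            binder = paste0(ex$allotype[pidx], "=strong")))
        }
      }
      assigned <- assigned[!duplicated(assigned$sequence), , drop = FALSE]
      prefix <- if (role == "benign") "B" else "T"
      sid <- sprintf("%s%02d", prefix, s)
      samples[[s]] <- assemble_sample(assigned, sid, paste0("D_", sid),
                                      if (role == "benign") "tissue" else "tumor",
                                      if (role == "benign") "benign" else "tumor",
                                      config$hla_class, typing[[s]], config)
    }
    pep_cohort(role, samples)
  }
  benign <- build_cohort("benign", config$n_benign, benign_typing, hk_in_benign)
  tumor <- build_cohort("tumor", config$n_tumor, tumor_typing, hk_in_tumor,
                        plant_members)
  list(proteome = proteome, benign = benign, tumor = tumor,
       truth = list(planted = do.call(rbind, plant_rows),
                    housekeeping = sort(unique(hk$sequence)),
                    warnings = warnings))
}

#' Generate an eluted/synthetic spectrum pair for a peptide
#'
#' Both spectra share one underlying fragment-intensity profile; the synthetic
#' spectrum's b/y m/z values carry the isotope label shift. Per-spectrum
#' log-normal multiplicative intensity noise and Poisson-count random noise
#' peaks are added.
#'
#' @param peptide amino-acid sequence.
#' @param label data.frame with `position` and `delta` (default: one label at
#'   the last residue with `config$label_delta`).
#' @param config a [generator_config()] (its seed is applied).
#' @return list with `eluted`, `synthetic` ([spectrum()]s) and `truth`
#'   (fragment table with the shared noise-free intensities).
#' @export
gen_spectrum_pair <- function(peptide, label = NULL, config = generator_config()) {
  set.seed(config$seed)
  if (is.null(label)) {
    label <- data.frame(position = nchar(peptide), delta = config$label_delta)
  }
  fr_plain <- theoretical_fragments(peptide)
  fr_label <- theoretical_fragments(peptide, label)
  base <- stats::rlnorm(nrow(fr_plain), meanlog = 7, sdlog = 0.8)

  make_spec <- function(frags, title) {
    noise_mult <- if (config$spectrum_noise_sd > 0) {
      stats::rlnorm(length(base), 0, config$spectrum_noise_sd)
    } else rep(1, length(base))
    n_noise <- stats::rpois(1L, config$noise_peaks)
    mz_range <- range(frags$mz)
    noise_mz <- stats::runif(n_noise, mz_range[1] * 0.8, mz_range[2] * 1.1)
    noise_int <- stats::runif(n_noise, 0, stats::quantile(base, 0.2))
    peaks <- rbind(cbind(frags$mz, base * noise_mult),
                   cbind(noise_mz, noise_int))
    prec <- (monoisotopic_mass(peptide) + 2 * PROTON_MASS) / 2
    spectrum(title, prec, 2L, peaks)
  }
  list(eluted = make_spec(fr_plain, paste0(peptide, "_eluted")),
       synthetic = make_spec(fr_label, paste0(peptide, "_synthetic")),
       truth = tibble::tibble(ion = fr_plain$ion, mz_eluted = fr_plain$mz,
                              mz_synthetic = fr_label$mz, base_intensity = base))
}
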