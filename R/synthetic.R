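# Synthetic fixtures: the packaged Balafon knowledge base, a seeded
# complaint generator with by-construction consistency labels, and
# rule-base coverage reports. Everything other modules need for testing is
# generated here in code; no external data is required.

#' Build the packaged Balafon knowledge base
#'
#' Constructs the fitting knowledge base for the Balafon hearing aid:
#'
#' * four electroacoustic parameters — MCL (alias `min_dyn`) and UCL
#'   (alias `max_dyn`) in the dynamic group with a 6 dB step unit, the
#'   volume step count `nb_vol`, and the silence-detection parameter
#'   `enerFaibl` (silence group, 1-unit step);
#' * two device profiles — the BTE model, which limits MCL to 70 dB despite
#'   the 0-120 dB typical range, and the body-worn model with the full
#'   range;
#' * the fitting guide: the 22 published rows (1-17, 19, 20, 23-25) plus 11
#'   synthetic placeholder entries (rows 18, 21, 22, 26-33) standing in for
#'   guide rows whose full wording is not transcribed here, marked
#'   `source = "synthetic_placeholder"`, bringing the guide to its 33
#'   complaint classes;
#' * two consistency rules, including the own-voice/radio/quiet-room
#'   screening example;
#' * the adjustment policy: 4-12 dB noticeable-gain range, 6 dB step unit.
#'
#' @return A validated `hafes_kb`.
#' @examples
#' kb <- build_balafon_fixture()
#' length(kb$guide)  # 33
#' @export
build_balafon_fixture <- function() {
  parameters <- list(
    parameter_spec("MCL", "dynamic", "dB", c(0, 120), 50, 6, "min_dyn"),
    parameter_spec("UCL", "dynamic", "dB", c(0, 140), 90, 6, "max_dyn"),
    parameter_spec("nb_vol", "volume", "", c(1, 10), 5, 1),
    parameter_spec("enerFaibl", "silence", "", c(0, 10), 5, 1)
  )
  devices <- list(
    device_profile("BalafonBTE", "BTE", list(MCL = c(0, 70))),
    device_profile("BalafonBody", "body")
  )

  quiet <- c(0L, 1L)   # very quiet + quiet
  noisy <- c(2L, 3L)   # noisy + very noisy
  txt <- function(en, fr) list(en = en, fr = fr)
  lower  <- txt("Lower the volume.", "Baissez le volume.")
  raise  <- txt("Increase the volume.", "Augmentez le volume.")
  ea <- function(param, dir, lev, prov = "expert")
    solution("EA", parameter = param, command = command(dir, lev),
             provenance = prov)

  g <- guide_entry
  guide <- list(
    g(1, list(cause = 0L), list(solution("C")), txt(
      "The hearing aid may be in standby mode. Restart (turn off and on) the hearing aid and check the battery level. Ensure that your hearing aid is on.",
      "L'appareil est peut-être en veille. Redémarrez (éteignez puis rallumez) l'appareil et vérifiez le niveau de la pile. Assurez-vous que votre appareil est allumé.")),
    g(2, list(cause = 5L, environment = quiet), list(ea("MCL", "decrease", 1)),
      txt("Do not worry, this is the intrinsic noise of the hearing aid.",
          "Ne vous inquiétez pas, il s'agit du bruit intrinsèque de l'appareil.")),
    g(3, list(cause = 3L, environment = quiet), list(solution("AP")), txt(
      "Check that your hearing aid is properly positioned in the ear.",
      "Vérifiez que votre appareil est bien positionné dans l'oreille.")),
    g(4, list(cause = 3L, environment = noisy), list(solution("AP")), txt(
      "Check that your hearing aid is properly positioned.",
      "Vérifiez que votre appareil est bien positionné.")),
    g(5, list(cause = 3L), list(ea("UCL", "decrease", 1)), lower),
    g(6, list(cause = 4L, environment = quiet),
      list(ea("MCL", "decrease", 1)), lower),
    g(7, list(cause = 4L, environment = noisy),
      list(ea("nb_vol", "increase", 1)), lower),
    g(8, list(cause = 10L), list(solution("T")), txt(
      "Follow a therapy. Please make an appointment with an audiologist.",
      "Suivez une thérapie. Veuillez prendre rendez-vous avec un audiologiste.")),
    g(9, list(cause = 1L, specificity = 1L),
      list(ea("UCL", "decrease", 1)), lower),
    g(10, list(cause = 1L, specificity = 2L, environment = quiet),
      list(ea("MCL", "decrease", 1)), lower),
    g(11, list(cause = 1L, environment = quiet),
      list(ea("UCL", "decrease", 1)), lower,
      alternative = list(
        note = "prose variant of this class names MCL (decrease-); the tabulated guide is operative",
        parameter = "MCL", command = "decrease-")),
    g(12, list(cause = 1L, environment = noisy), list(solution("C")), txt(
      "Lower the volume, reduce sensitivity.",
      "Baissez le volume, réduisez la sensibilité.")),
    g(13, list(cause = 1L), list(ea("MCL", "decrease", 2)), lower),
    g(14, list(cause = 2L, specificity = 1L, environment = quiet),
      list(ea("UCL", "increase", 2)), raise),
    g(15, list(cause = 2L, specificity = 1L, environment = noisy),
      list(ea("MCL", "decrease", 2))),
    g(16, list(cause = 2L, specificity = 1L),
      list(ea("UCL", "increase", 2)), raise),
    g(17, list(cause = 2L, specificity = 2L, environment = quiet),
      list(ea("MCL", "increase", 1)), raise),
    g(18, list(cause = 2L, specificity = 2L, environment = noisy),
      list(ea("MCL", "increase", 1)), raise, source = "synthetic_placeholder"),
    g(19, list(cause = 2L, specificity = 2L),
      list(ea("MCL", "increase", 1)), raise),
    g(20, list(cause = 2L, environment = quiet),
      list(ea("MCL", "increase", 2))),
    g(21, list(cause = 2L, environment = noisy),
      list(solution("R", advice = txt(
        "Increase the volume with the volume control.",
        "Augmentez le volume avec la molette de volume."))),
      source = "synthetic_placeholder"),
    g(22, list(cause = 2L), list(ea("MCL", "increase", 2)), raise,
      source = "synthetic_placeholder"),
    g(23, list(cause = 9L, environment = quiet),
      list(ea("enerFaibl", "decrease", 2, prov = "manufacturer"))),
    g(24, list(cause = 9L, environment = noisy),
      list(ea("enerFaibl", "decrease", 4, prov = "manufacturer"))),
    g(25, list(cause = 9L),
      list(ea("enerFaibl", "decrease", 2, prov = "manufacturer"))),
    g(26, list(cause = 7L), list(solution("AP")), txt(
      "Have the earmold venting checked.",
      "Faites vérifier l'évent de l'embout."), source = "synthetic_placeholder"),
    g(27, list(cause = 8L), list(solution("AP")), txt(
      "Clean the earpiece and replace the wax filter.",
      "Nettoyez l'embout et remplacez le filtre anti-cérumen."),
      source = "synthetic_placeholder"),
    g(28, list(cause = 6L), list(solution("AC")), txt(
      "Hearing your own voice louder is common at first; allow an adjustment period.",
      "Entendre sa propre voix plus fort est courant au début ; prévoyez une période d'adaptation."),
      source = "synthetic_placeholder"),
    g(29, list(cause = 11L), list(solution("C")), txt(
      "Please consult a hearing care professional.",
      "Veuillez consulter un professionnel de l'audition."),
      source = "synthetic_placeholder"),
    g(30, list(cause = 13L), list(solution("AP")), txt(
      "Check the battery and its contacts.",
      "Vérifiez la pile et ses contacts."), source = "synthetic_placeholder"),
    g(31, list(cause = 14L), list(solution("C")), txt(
      "Please consult a hearing care professional about the fit.",
      "Veuillez consulter un professionnel de l'audition au sujet de l'ajustement."),
      source = "synthetic_placeholder"),
    g(32, list(cause = 16L), list(solution("AP")), txt(
      "Have the earpiece refitted.",
      "Faites réajuster l'embout."), source = "synthetic_placeholder"),
    g(33, list(cause = 17L), list(solution("R", advice = txt(
      "Open the battery door overnight and keep spare batteries at hand.",
      "Ouvrez le tiroir pile la nuit et gardez des piles de rechange."))),
      source = "synthetic_placeholder")
  )

  rules <- list(
    consistency_rule(
      "own_voice_radio_quiet",
      list(cause = 6L, activity = 4L, environment = c(0L, 1L)),
      txt("An own-voice complaint while listening to the radio in a quiet room is logically inconsistent.",
          "Une plainte sur sa propre voix en écoutant la radio dans une pièce calme est logiquement incohérente.")),
    consistency_rule(
      "no_sound_but_specific",
      list(cause = 0L, specificity = 1:6),
      txt("Reporting no sound at all while naming specific problem sounds is logically inconsistent.",
          "Déclarer n'entendre aucun son tout en désignant des sons précis est logiquement incohérent."))
  )

  knowledge_base(version = "1.0", parameters = parameters,
                 devices = devices, guide = guide,
                 consistency_rules = rules,
                 policy = adjustment_policy(c(4, 12), 6))
}

#' Configuration for the synthetic complaint generator
#'
#' @param seed integer RNG seed; the generator is reproducible under a
#'   fixed seed.
#' @param n number of complaints to generate.
#' @param p_inconsistent probability in `[0, 1]` that an item instantiates
#'   a packaged consistency-rule pattern (and is labelled inconsistent).
#' @param weights optional named list of per-dimension categorical sampling
#'   weights (default uniform).
#' @return Object of class `hafes_generator_config`.
#' @export
generator_config <- function(seed = 1L, n = 100L, p_inconsistent = 0,
                             weights = NULL) {
  n <- as_scalar_int(n, "n")
  if (n < 0L) hafes_abort("n must be >= 0", "hafes_validation_error")
  p_inconsistent <- as_scalar_num(p_inconsistent, "p_inconsistent")
  if (p_inconsistent < 0 || p_inconsistent > 1)
    hafes_abort("p_inconsistent must be in [0, 1]",
                "hafes_validation_error")
  structure(list(seed = as_scalar_int(seed, "seed"), n = n,
                 p_inconsistent = p_inconsistent, weights = weights),
            class = "hafes_generator_config")
}

sample_code <- function(size, weights = NULL) {
  sample.int(size, 1L, prob = weights) - 1L
}

#' Generate labelled synthetic complaints
#'
#' Draws `cfg$n` complaints from the questionnaire code space. With
#' probability `cfg$p_inconsistent` an item instantiates the pattern of a
#' (uniformly chosen) packaged consistency rule and is labelled
#' inconsistent by construction; otherwise codes are drawn from the
#' per-dimension distributions (uniform by default) and re-drawn until the
#' complaint passes screening, so the label always agrees with
#' [check_consistency()].
#'
#' @param cfg a [generator_config()].
#' @param schema a `hafes_questionnaire`.
#' @param rules consistency rules to label against; defaults to the Balafon
#'   fixture's rules.
#' @return Data frame with the six code columns and a logical
#'   `inconsistent` label column.
#' @examples
#' head(generate_complaints(generator_config(seed = 42, n = 5)))
#' @export
generate_complaints <- function(cfg = generator_config(),
                                schema = get_questionnaire(),
                                rules = NULL) {
  stopifnot(inherits(cfg, "hafes_generator_config"))
  rules <- rules %||% build_balafon_fixture()$consistency_rules
  sizes <- schema$sizes
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  draw <- function() {
    codes <- vapply(.hafes_dimensions, function(d)
      sample_code(sizes[[d]], cfg$weights[[d]]), integer(1))
    as_complaint(codes)
  }
  rows <- vector("list", cfg$n)
  labels <- logical(cfg$n)
  for (i in seq_len(cfg$n)) {
    make_bad <- length(rules) > 0 && stats::runif(1) < cfg$p_inconsistent
    if (make_bad) {
      r <- rules[[sample.int(length(rules), 1L)]]
      codes <- vapply(.hafes_dimensions, function(d) {
        allowed <- r$pattern[[d]]
        if (is.null(allowed)) sample_code(sizes[[d]], cfg$weights[[d]])
        else allowed[sample.int(length(allowed), 1L)]
      }, integer(1))
      c0 <- as_complaint(codes)
      labels[i] <- TRUE
    } else {
      repeat {
        c0 <- draw()
        if (check_consistency(c0, rules)$consistent) break
      }
      labels[i] <- FALSE
    }
    rows[[i]] <- unclass(c0)
  }
  out <- as.data.frame(do.call(rbind, rows))
  if (cfg$n == 0L)
    out <- as.data.frame(setNames(rep(list(integer()), 6),
                                  .hafes_dimensions))
  out$inconsistent <- labels
  out
}

# per-entry hit counts over a complaint data frame (names = entry ids)
coverage_counts <- function(kb, complaints) {
  ids <- match_space(kb, complaints)
  tab <- table(factor(ids[!is.na(ids)],
                      levels = sort(vapply(kb$guide, function(g) g$id,
                                           integer(1)))))
  setNames(as.integer(tab), names(tab))
}

#' Rule-base coverage report
#'
#' Tallies, per guide entry, how many complaints in a sample (or in the
#' full nature/context enumeration) the entry wins, plus the count and
#' fraction of consultation fallbacks. Entries with zero hits under full
#' enumeration are flagged: they are unreachable by any encodable
#' complaint.
#'
#' @param kb a `hafes_kb`.
#' @param complaints data frame of complaint codes (as produced by
#'   [generate_complaints()] or [complaint_space()]); ignored when
#'   `full = TRUE`.
#' @param full tally over the full enumerated complaint space?
#' @return Object of class `hafes_coverage`: list with `hits` (data frame
#'   of `entry_id`, `hits`), `fallback_count`, `fallback_fraction`, `n`,
#'   `unreachable` (entry ids with zero hits).
#' @export
coverage_report <- function(kb, complaints = NULL, full = FALSE) {
  if (full) complaints <- complaint_space()
  if (is.null(complaints))
    hafes_abort("supply complaints or set full = TRUE",
                "hafes_usage_error")
  n <- nrow(complaints)
  counts <- coverage_counts(kb, complaints)
  fallback <- n - sum(counts)
  structure(list(
    hits = data.frame(entry_id = as.integer(names(counts)),
                      hits = as.integer(counts)),
    fallback_count = fallback,
    fallback_fraction = if (n > 0) fallback / n else 0,
    n = n,
    unreachable = as.integer(names(counts))[counts == 0L]
  ), class = "hafes_coverage")
}

#' @export
print.hafes_coverage <- function(x, ...) {
  cat(sprintf(
    "Coverage over %d complaints: %d entries hit, %d fallbacks (%.1f%%)\n",
    x$n, sum(x$hits$hits > 0), x$fallback_count,
    100 * x$fallback_fraction))
  if (length(x$unreachable))
    cat("  entries with zero hits:",
        paste(x$unreachable, collapse = ", "), "\n")
  invisible(x)
}
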