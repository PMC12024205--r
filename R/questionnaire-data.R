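# Packaged item catalogs for the six-question self-assessment instrument.
#
# The instrument has three sections:
#   nature of the complaint : cause, specificity
#   listening context       : environment, activity
#   impact assessment       : frequency, discomfort
#
# Codes are 0-based consecutive integers in catalog order and are identical
# across locales; only the labels are localized. Catalog sizes are fixed at
# cause 18, specificity 7, environment 5, activity 8, frequency 7,
# discomfort 3.

.hafes_dimensions <- c("cause", "specificity", "environment", "activity",
                       "frequency", "discomfort")

.hafes_sections <- list(
  nature_of_complaint = c("cause", "specificity"),
  listening_context   = c("environment", "activity"),
  impact_assessment   = c("frequency", "discomfort")
)

.hafes_catalogs <- list(
  cause = list(
    en = c(
      "I cannot hear any sound",
      "The sound is too loud",
      "The sound is too soft",
      "The hearing aid whistles",
      "I hear a lot of noise",
      "I hear wind noise",
      "My own voice sounds noisy",
      "Sounds echo",
      "Sounds are muffled",
      "The sound cuts out",
      "I hear but I do not understand",
      "The sound is distorted",
      "Sounds are metallic",
      "I hear buzzing or humming",
      "The hearing aid hurts my ear",
      "My ear itches",
      "The earpiece does not stay in my ear",
      "The battery drains too quickly"
    ),
    fr = c(
      "Je n'entends aucun son",
      "Le son est trop fort",
      "Le son est trop faible",
      "L'appareil siffle",
      "J'entends beaucoup de bruit",
      "J'entends un bruit de vent",
      "Ma propre voix est bruyante",
      "Les sons résonnent",
      "Les sons sont étouffés",
      "Le son se coupe",
      "J'entends mais je ne comprends pas",
      "Le son est déformé",
      "Les sons sont métalliques",
      "J'entends un bourdonnement",
      "L'appareil me fait mal à l'oreille",
      "Mon oreille me démange",
      "L'embout ne tient pas dans l'oreille",
      "La pile s'use trop vite"
    )
  ),
  specificity = list(
    en = c(
      "All sounds / not specific",
      "Loud sounds",
      "Soft sounds",
      "Speech and voices",
      "My own voice",
      "Music",
      "High-pitched sounds"
    ),
    fr = c(
      "Tous les sons / non spécifique",
      "Les sons forts",
      "Les sons faibles",
      "La parole et les voix",
      "Ma propre voix",
      "La musique",
      "Les sons aigus"
    )
  ),
  environment = list(
    en = c(
      "Very quiet (0-20 dB)",
      "Quiet (25-60 dB)",
      "Noisy (65-80 dB)",
      "Very noisy (90-140 dB)",
      "Varies / unspecified"
    ),
    fr = c(
      "Très calme (0-20 dB)",
      "Calme (25-60 dB)",
      "Bruyant (65-80 dB)",
      "Très bruyant (90-140 dB)",
      "Variable / non précisé"
    )
  ),
  activity = list(
    en = c(
      "Unspecified / daily life",
      "Conversation with one person",
      "Conversation in a group",
      "Conversation on the phone",
      "Listening to the radio",
      "Watching television",
      "Walking outdoors",
      "Travelling in a vehicle"
    ),
    fr = c(
      "Non précisé / vie quotidienne",
      "Conversation avec une personne",
      "Conversation en groupe",
      "Conversation au téléphone",
      "Écoute de la radio",
      "Regarder la télévision",
      "Promenade à l'extérieur",
      "Déplacement en véhicule"
    )
  ),
  frequency = list(
    en = c("Never", "Rarely", "Occasionally", "Often", "Usually",
           "Almost always", "Always"),
    fr = c("Jamais", "Rarement", "Occasionnellement", "Souvent",
           "Habituellement", "Presque toujours", "Toujours")
  ),
  discomfort = list(
    en = c("Tolerable", "Annoying", "Unbearable"),
    fr = c("Tolérable", "Gênant", "Insupportable")
  )
)

# frequency and discomfort are ordinal scales; recorded for downstream
# priority use (urgency metadata on recommendations)
.hafes_ordinal_dimensions <- c("frequency", "discomfort")

# environment dB bands. The printed anchors (0-20, 25-60, 65-80, 90-140)
# leave gaps; each band's upper edge is extended to the next band's lower
# anchor so the classifier is total: [0,20], (20,60], (60,80], (80,Inf).
# Codes are the environment catalog codes; item 4 ("varies/unspecified")
# is never produced by level classification.
.hafes_env_bands <- data.frame(
  code  = 0:3,
  name  = c("very_quiet", "quiet", "noisy", "very_noisy"),
  lower = c(0, 20, 60, 80),
  upper = c(20, 60, 80, Inf),
  stringsAsFactors = FALSE
)

.hafes_locales <- c("en", "fr")

catalog_sizes <- function() {
  vapply(.hafes_catalogs, function(cat) length(cat$en), integer(1))
}
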