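# Internal phrase banks used by the synthetic-corpus generator. The three
# sentiment banks use disjoint vocabularies: every positive phrase carries at
# least one strongly positive lexicon word, every negative phrase a strongly
# negative one, and neutral phrases carry no valenced word at all, so that
# both the built-in lexicon scorers and the keyword-oracle test doubles agree
# with the ground-truth label on generated text. None of the banks contain
# theme keywords or AEFI terms; those are embedded separately.

sentiment_phrase_bank <- list(
  positive = c(
    "so grateful to get my dose today, feeling great",
    "what a relief, the rollout here has been brilliant",
    "happy and thankful for the wonderful team at the centre",
    "feeling excellent after my appointment, love the efficiency",
    "such good news this week, gives me real hope",
    "delighted with how smooth everything was, superb staff"
  ),
  negative = c(
    "this is awful, i have felt terrible since yesterday",
    "really scared and worried about what comes next",
    "angry about the queues, such a horrible mess",
    "furious with how this was handled, a dreadful shambles",
    "feeling miserable about the whole situation, grim week",
    "i hate how confusing this is, utterly frustrating"
  ),
  neutral = c(
    "booked the appointment for tuesday morning",
    "the centre opens at nine according to the letter",
    "second dose is scheduled in twelve weeks",
    "saw the update on the council website earlier",
    "the form asks for a reference number and postcode",
    "the queue moved along, took about twenty minutes"
  )
)

# Marker words that identify each sentiment bank; used by the deterministic
# keyword-oracle scorers and kept in sync with the phrases above.
sentiment_marker_words <- list(
  positive = c("grateful", "great", "relief", "brilliant", "happy", "thankful",
               "wonderful", "excellent", "love", "good", "hope", "delighted",
               "smooth", "superb"),
  negative = c("awful", "terrible", "scared", "worried", "angry", "horrible",
               "furious", "dreadful", "shambles", "miserable", "grim", "hate",
               "frustrating")
)

# Terms the generator embeds when a post mentions an AEFI group. Each entry
# is drawn from the default counting lexicon (see default_aefi_lexicon())
# and chosen to match exactly ONE lexicon term, so a mentioned group
# contributes exactly one counted mention and group probabilities are
# recoverable from mention shares.
aefi_phrase_bank <- list(
  appetite = c("appetite"),
  allergy = c("allergy", "anaphylaxis"),
  injection_site = c("injection site", "sore arm"),
  clots = c("thrombosis", "clots"),
  bell_palsy = c("bell palsy", "facial droop"),
  guillain_barre = c("guillain-barre", "guillain barre"),
  headache = c("headache", "migraine"),
  fever = c("fever", "high temperature"),
  diarrhea = c("diarrhea", "diarrhoea"),
  generalized = c("lethargy", "muscle ache", "flu", "vomit", "nausea")
)

# Stage keywords the generator embeds in theme-passing posts; drawn from the
# default filter lexicons.
theme_stage1_bank <- c("covid", "covid19", "coronavirus")
theme_stage2_bank <- c("vaccine", "vaccination", "jab", "astrazeneca",
                       "pfizer", "moderna")

# Neutral filler clauses; deliberately free of theme keywords, AEFI terms and
# valenced words so they never perturb filtering, counting or scoring.
filler_bank <- c(
  "just sharing what i heard from the neighbours",
  "posting this before heading back to work",
  "the bus into town was on time for once",
  "my sister mentioned this over the phone last night",
  "went past the community hall on the school run",
  "reading the local paper with a cup of tea",
  "the kids are back at their clubs this month",
  "long day, but wanted to put this here"
)

offtopic_country_bank <- c("US", "IE", "FR", NA_character_)
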