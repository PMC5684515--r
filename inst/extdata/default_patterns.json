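[
  {
    "pattern_id": 1,
    "simplified_form": "(im|i am|i'm).*[time].*pregnant",
    "realized_expression": "(?=.*\\b(im|i am|i'm)\\b)(?=.*\\b(week|weeks|month|months|day|days)\\b)(?=.*\\bpregnant\\b)",
    "notes": "time unit: week(s), month(s) or day(s); term groups in any order"
  },
  {
    "pattern_id": 2,
    "simplified_form": "baby & arriving",
    "realized_expression": "(?=.*\\bbaby\\b)(?=.*\\barriving\\b)",
    "notes": "both terms present, any order"
  },
  {
    "pattern_id": 3,
    "simplified_form": "baby coming soon",
    "realized_expression": "\\bbaby[[:space:][:punct:]]+coming[[:space:][:punct:]]+soon\\b",
    "notes": "exact sequence, whitespace or punctuation between terms"
  },
  {
    "pattern_id": 4,
    "simplified_form": "been.*[time] & since & i & pregnant",
    "realized_expression": "(?=.*\\bbeen\\b.*\\b(day|days|week|weeks|month|months)\\b)(?=.*\\bsince\\b)(?=.*\\bi\\b)(?=.*\\bpregnant\\b)",
    "notes": "'been ... [time]' in order; since, i, pregnant anywhere"
  },
  {
    "pattern_id": 5,
    "simplified_form": "growing & baby & belly",
    "realized_expression": "(?=.*\\bgrowing\\b)(?=.*\\bbaby\\b)(?=.*\\bbelly\\b)",
    "notes": "all three terms present, any order"
  },
  {
    "pattern_id": 6,
    "simplified_form": "(im|i am|i'm) expecting.*baby",
    "realized_expression": "\\b(im|i am|i'm)\\b[[:space:][:punct:]]+expecting\\b.*\\bbaby\\b",
    "notes": "exact sequence for the announcement; 'baby' anywhere after"
  },
  {
    "pattern_id": 7,
    "simplified_form": "(im|i am|i'm) going to (b|be) a mom",
    "realized_expression": "\\b(im|i am|i'm)\\b[[:space:][:punct:]]+going[[:space:][:punct:]]+to[[:space:][:punct:]]+(b|be)[[:space:][:punct:]]+a[[:space:][:punct:]]+mom\\b",
    "notes": "exact sequence, whitespace or punctuation between terms"
  },
  {
    "pattern_id": 8,
    "simplified_form": "(im|i am|i'm) having a baby",
    "realized_expression": "\\b(im|i am|i'm)\\b[[:space:][:punct:]]+having[[:space:][:punct:]]+a[[:space:][:punct:]]+baby\\b",
    "notes": "exact sequence, whitespace or punctuation between terms"
  },
  {
    "pattern_id": 9,
    "simplified_form": "i (hav|have) been pregnant",
    "realized_expression": "\\bi[[:space:][:punct:]]+(hav|have)[[:space:][:punct:]]+been[[:space:][:punct:]]+pregnant\\b",
    "notes": "exact sequence, whitespace or punctuation between terms"
  },
  {
    "pattern_id": 10,
    "simplified_form": "(ive|i've) been pregnant",
    "realized_expression": "\\b(ive|i've)[[:space:][:punct:]]+been[[:space:][:punct:]]+pregnant\\b",
    "notes": "exact sequence, whitespace or punctuation between terms"
  },
  {
    "pattern_id": 11,
    "simplified_form": "adding & one & \"our family\"",
    "realized_expression": "(?=.*\\badding\\b)(?=.*\\bone\\b)(?=.*\\bour[[:space:][:punct:]]+family\\b)",
    "notes": "'our family' as a sequence; adding, one anywhere"
  },
  {
    "pattern_id": 12,
    "simplified_form": "my pregnancy",
    "realized_expression": "\\bmy[[:space:][:punct:]]+pregnancy\\b",
    "notes": "exact sequence, whitespace or punctuation between terms"
  },
  {
    "pattern_id": 13,
    "simplified_form": "(im|i am|i'm) going to have a baby",
    "realized_expression": "\\b(im|i am|i'm)\\b[[:space:][:punct:]]+going[[:space:][:punct:]]+to[[:space:][:punct:]]+have[[:space:][:punct:]]+a[[:space:][:punct:]]+baby\\b",
    "notes": "exact sequence, whitespace or punctuation between terms"
  },
  {
    "pattern_id": 14,
    "simplified_form": "our family.*growing.*(2|two) feet",
    "realized_expression": "\\bour[[:space:][:punct:]]+family\\b.*\\bgrowing\\b.*\\b(2|two)[[:space:][:punct:]]+feet\\b",
    "notes": "ordered: our family ... growing ... (2|two) feet"
  }
]
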