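{
  "comment": [
    "Shipped vocabulary and rule set for explicit prescribing-appropriateness",
    "screening of middle-aged adults on dispensing claims.",
    "Drug lists cover only the classes the shipped rules and the synthetic",
    "generator need, in both coding dialects (ATC prefixes; BNF dotted",
    "section codes). BNF sub-section splits marked *synthetic* are",
    "placeholder codes, as are the maintenance-dose thresholds, which are",
    "formulary-derived defaults (the criteria themselves do not print them).",
    "Every field is user-overridable by passing an edited copy of this file",
    "to load_vocabulary()."
  ],
  "classes": [
    {"id": "strong_opioids", "label": "Strong opioids",
     "atc_prefixes": ["N02AA", "N02AB", "N02AE"], "bnf_prefixes": ["4.7.2"]},
    {"id": "osmotic_laxatives", "label": "Osmotic laxatives",
     "atc_prefixes": ["A06AD"], "bnf_prefixes": ["1.6.4"]},
    {"id": "stimulant_laxatives", "label": "Stimulant laxatives",
     "atc_prefixes": ["A06AB"], "bnf_prefixes": ["1.6.2"]},
    {"id": "ppi", "label": "Proton pump inhibitors",
     "atc_prefixes": ["A02BC"], "bnf_prefixes": ["1.3.5"]},
    {"id": "benzodiazepines", "label": "Benzodiazepines",
     "atc_prefixes": ["N05BA", "N05CD"], "bnf_prefixes": ["4.1.2"]},
    {"id": "z_drugs", "label": "Non-benzodiazepine hypnotics (Z-drugs)",
     "atc_prefixes": ["N05CF"], "bnf_prefixes": ["4.1.1"]},
    {"id": "first_gen_antihistamines",
     "label": "First-generation (sedating) antihistamines",
     "atc_prefixes": ["R06AB", "R06AD"], "bnf_prefixes": ["3.4.1.1"],
     "granularity_note": "BNF sub-section split is synthetic"},
    {"id": "second_gen_antihistamines",
     "label": "Second-generation (non-sedating) antihistamines",
     "atc_prefixes": ["R06AE", "R06AX"], "bnf_prefixes": ["3.4.1.2"],
     "granularity_note": "BNF sub-section split is synthetic"},
    {"id": "nsaids", "label": "Non-steroidal anti-inflammatory drugs",
     "atc_prefixes": ["M01AE", "M01AB", "M01AC"], "bnf_prefixes": ["10.1.1"]},
    {"id": "tca", "label": "Tricyclic antidepressants",
     "atc_prefixes": ["N06AA"], "bnf_prefixes": ["4.3.1"]},
    {"id": "ssri", "label": "Selective serotonin reuptake inhibitors",
     "atc_prefixes": ["N06AB"], "bnf_prefixes": ["4.3.3"]},
    {"id": "statins", "label": "HMG-CoA reductase inhibitors",
     "atc_prefixes": ["C10AA"], "bnf_prefixes": ["2.12"]},
    {"id": "ace_inhibitors", "label": "ACE inhibitors",
     "atc_prefixes": ["C09AA"], "bnf_prefixes": ["2.5.5.1"]},
    {"id": "beta_blockers", "label": "Beta-adrenoceptor blockers",
     "atc_prefixes": ["C07AB"], "bnf_prefixes": ["2.4"]},
    {"id": "biguanides", "label": "Biguanides",
     "atc_prefixes": ["A10BA"], "bnf_prefixes": ["6.1.2.2"]},
    {"id": "thyroid_hormones", "label": "Thyroid hormones",
     "atc_prefixes": ["H03AA"], "bnf_prefixes": ["6.2.1"]},
    {"id": "calcium_channel_blockers", "label": "Calcium-channel blockers",
     "atc_prefixes": ["C08CA"], "bnf_prefixes": ["2.6.2"]}
  ],
  "dose_thresholds": [
    {"system": "ATC", "prefix": "A02BC",   "maintenance_mg_per_day": 20},
    {"system": "ATC", "prefix": "A02BC01", "maintenance_mg_per_day": 20},
    {"system": "ATC", "prefix": "A02BC03", "maintenance_mg_per_day": 15},
    {"system": "BNF", "prefix": "1.3.5",   "maintenance_mg_per_day": 20}
  ],
  "criteria": [
    {"criterion_id": "opioid_no_laxative", "category": "CO_PRESCRIPTION",
     "target_class": "strong_opioids",
     "required_classes": ["osmotic_laxatives", "stimulant_laxatives"],
     "window": "same_month",
     "label": "Strong opioid without co-prescribed osmotic or stimulant laxative"},
    {"criterion_id": "ppi_high_dose_gt8w", "category": "DOSE_DURATION",
     "target_class": "ppi", "max_duration_days": 56,
     "label": "PPI above maintenance dosage for >8 weeks"},
    {"criterion_id": "benzo_gt_4w", "category": "DURATION",
     "target_class": "benzodiazepines", "max_duration_days": 28,
     "label": "Benzodiazepine used for >4 weeks"},
    {"criterion_id": "first_gen_antihistamine_first_line_gt7d",
     "category": "FIRST_LINE", "target_class": "first_gen_antihistamines",
     "max_duration_days": 7,
     "preferred_alternative_classes": ["second_gen_antihistamines"],
     "label": "First-generation antihistamine first-line for >7 days"},
    {"criterion_id": "zdrug_gt_4w", "category": "DURATION",
     "target_class": "z_drugs", "max_duration_days": 28,
     "label": "Non-benzodiazepine hypnotic used for >4 weeks"},
    {"criterion_id": "nsaid_gt_3m", "category": "DURATION",
     "target_class": "nsaids", "max_duration_days": 90,
     "label": "NSAID used for >3 months"},
    {"criterion_id": "tca_first_line", "category": "FIRST_LINE",
     "target_class": "tca",
     "preferred_alternative_classes": ["ssri"],
     "label": "TCA used first-line in treatment of depression"},
    {"criterion_id": "dup_opioids", "category": "DUPLICATION",
     "target_class": "strong_opioids",
     "label": "Duplicate opioids within one month"},
    {"criterion_id": "dup_benzodiazepines", "category": "DUPLICATION",
     "target_class": "benzodiazepines",
     "label": "Duplicate benzodiazepines within one month"},
    {"criterion_id": "dup_nsaids", "category": "DUPLICATION",
     "target_class": "nsaids",
     "label": "Duplicate NSAIDs within one month"},
    {"criterion_id": "dup_stimulant_laxatives", "category": "DUPLICATION",
     "target_class": "stimulant_laxatives",
     "label": "Duplicate stimulant laxatives within one month"}
  ]
}
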