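# Expected factor-by-diagnosis margins of the 21-implant study cohort:
# one row per factor level, counts in the peri-implantitis and mucositis
# groups.
fixture_margins <- function() {
  tibble::tribble(
    ~factor,              ~level,     ~implantitis, ~mucositis,
    "sex",                "F",        0L,  7L,
    "sex",                "M",        4L, 10L,
    "suppuration",        "absent",   4L, 17L,
    "suppuration",        "present",  0L,  0L,
    "pdl_history",        "Score 0",  1L,  8L,
    "pdl_history",        "Score 1",  0L,  5L,
    "pdl_history",        "Score 2",  0L,  0L,
    "pdl_history",        "Score 3",  3L,  4L,
    "plaque_status",      "Score 0",  0L,  4L,
    "plaque_status",      "Score 1",  1L,  8L,
    "plaque_status",      "Score 2",  3L,  3L,
    "plaque_status",      "Score 3",  0L,  2L,
    "gingival_status",    "Score 0",  0L, 11L,
    "gingival_status",    "Score 1",  2L,  2L,
    "gingival_status",    "Score 2",  2L,  4L,
    "gingival_status",    "Score 3",  0L,  0L,
    "diabetes",           "absent",   4L, 17L,
    "diabetes",           "present",  0L,  0L,
    "smoking",            "absent",   2L, 15L,
    "smoking",            "present",  2L,  2L,
    "residual_cement",    "absent",   4L, 17L,
    "residual_cement",    "present",  0L,  0L,
    "occlusal_overload",  "absent",   3L, 16L,
    "occlusal_overload",  "present",  1L,  1L,
    "keratinized_width",  "absent",   2L, 14L,
    "keratinized_width",  "present",  2L,  3L,
    "others",             "absent",   1L, 14L,
    "others",             "present",  3L,  3L,
    "result",             "low",      1L, 14L,
    "result",             "moderate", 3L,  3L)
}
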