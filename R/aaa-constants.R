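# Fixed nine-site thoracic layout: marker labels and their region grouping.

MARKER_LABELS <- paste0("M", 1:9)

MARKER_REGIONS <- c(
  M1 = "upper", M2 = "upper", M3 = "upper",
  M4 = "middle", M5 = "middle", M6 = "middle",
  M7 = "lower", M8 = "lower", M9 = "lower"
)
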