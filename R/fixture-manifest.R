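# md5 sums of the packaged reference CSVs, frozen when the tables were
# transcribed. load_fixture() compares against these so that a corrupted
# or locally edited copy fails loudly instead of silently shifting every
# downstream index.
fixture_manifest <- function() {
  c(
    "table1_temperature.csv" = "738224dcc54f745bf004b471cea2b543",
    "table1_pH.csv"          = "c14d464a93f426e42f881a85977648a1",
    "table2_temperature.csv" = "a5d4190e1aa2c8f49adc3df737779327",
    "table2_pH.csv"          = "92bcfded178213e9c58ed85f75126c85",
    "table3_temperature.csv" = "228e091a52ea962b46f5b713d01f10fe",
    "table3_pH.csv"          = "152030d92f17bce9b52111a958751744",
    "table4_temperature.csv" = "4ddd26d14ab557d9b3506e0a5996a096",
    "table4_pH.csv"          = "9998258130e7c69e53d35a3422aa6bf7",
    "table5_temperature.csv" = "3c8b6fcb534ba39d631881ce0a1bce94",
    "table5_pH.csv"          = "27da007ac8242f4190361c61a4a6687f",
    "table6_temperature.csv" = "e6c813a3c8e9454330103feeb4696371",
    "table6_pH.csv"          = "aeeddd13e9dd8556b7a1569023cae0d2"
  )
}
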