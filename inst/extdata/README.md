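# extdata

Place a per-subject feature/outcome table at `s1_subject_table.csv` to
enable the published-table reproduction tests and `reproduceTables()`
without a column map. Expected layout (see `defaultColumnMap()`): columns
`id`, `time` (DFS months), `event` (1 = recurrence or death, 0 =
censored), and liver-normalized feature columns prefixed `t0_`, `t1_` and
`delta_` over the names of `featureNames()`, with `delta_* = t0_* - t1_*`
and NA in `t1_`/`delta_` columns for complete responders. Files with other
column names can be read by editing the column map passed to
`readCohortCSV()`.
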