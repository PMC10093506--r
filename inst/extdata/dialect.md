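# ICSR tabular dialect

An ICSR store is three UTF-8 delimited tables (comma by default, tab
accepted) with mandatory header rows, joined on `report_id`. Missing
optional values are empty cells (never the literal `NA`). Dates are
ISO-8601 (`YYYY-MM-DD`); partial dates are not representable and must be
left empty.

## reports.csv

| column      | type / values |
|-------------|---------------|
| report_id   | unique identifier |
| report_date | date |
| country     | ISO-like country code |
| reporter    | physician, pharmacist, other_health_professional, consumer, unknown |
| age_years   | nonnegative number, optional |
| sex         | male, female, unknown |
| seriousness | serious, not_serious, unknown |

## drugs.csv (one row per drug entry, >= 1 per report)

| column       | type / values |
|--------------|---------------|
| report_id    | foreign key |
| drug_code    | opaque (ATC-like) identifier |
| role         | suspected, interacting, concomitant |
| start_date   | date, optional |
| action_taken | withdrawn, dose_reduced, continued, unknown |
| indication   | free text, optional |

## reactions.csv (one row per reaction entry, >= 1 per report)

| column        | type / values |
|---------------|---------------|
| report_id     | foreign key |
| pt_code       | preferred-term code from the dictionary |
| onset_date    | date, optional |
| outcome       | recovered, recovering, not_recovered, recovered_with_sequelae, fatal, unknown |
| serious_flags | pipe-joined subset of hospitalization, life_threatening, death, disability, congenital_anomaly, other_medically_significant; empty = none |

Consistency rules enforced on read: any serious flag implies report
`seriousness = serious`; a fatal reaction outcome implies the `death`
flag somewhere on the report and `seriousness = serious`.

# Term dictionary dialect

Two delimited tables: `terms.csv` (`code,name,level` with level in
SOC, HLGT, HLT, PT) and `links.csv` (`child_code,parent_code`), links
joining adjacent levels only (the HLGT layer is optional for an HLT).
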