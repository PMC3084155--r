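# Bundled data

## `ledger_programme.csv`, `ledger_usual.csv`

Micro-costing ledgers of the comprehensive hypertension programme and of
usual care, in 2010 International Dollars. Columns: `item`, `category`
(labour / capital / land / resource are institution-level annual items;
overhead / visit / consumption are per patient-year), `unit_cost`,
`quantity`, and for capital rows `capital_lifetime` (years) and
`capital_rate` (annual discount rate for the equivalent annual cost).

Conventions:

- Capital items are annuitised over 5 years at 5% with an annuity-due
  factor (`htncea::equivalent_annual_cost()`).
- Land is priced per m2-month; quantities are stored annualised
  (e.g. a 7.50 m2 office -> 90 m2-months/year) so that
  `unit_cost * quantity` is the annual cost for every non-capital row.
- Most unit costs are as published, rounded to 2 decimals. For the telephone
  and overhead rows that rounding is too coarse to reproduce the published
  subtotals, so the stored unit cost is back-derived at full precision as
  published annual cost / published quantity.
- Consumption rows are annual per-patient amounts stored with quantity 1.
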