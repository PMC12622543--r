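{
  "planted_mqtls": [
    {
      "metabolite": "met001",
      "variant_id": "chr01_000074362",
      "variance_fraction": 0.280368527821265,
      "sign": 1
    },
    {
      "metabolite": "met002",
      "variant_id": "chr01_000046208",
      "variance_fraction": 0.0748823794396594,
      "sign": 1
    }
  ],
  "marker_metabolites": [
    {
      "metabolite": "met001",
      "sign": -1
    },
    {
      "metabolite": "met002",
      "sign": 1
    }
  ],
  "planted_eqtls": [
    {
      "gene_id": "gene0003",
      "variant_id": "chr01_000046208",
      "type": "cis",
      "variance_fraction": 0.149764758879319
    }
  ],
  "modules": {
    "gene0001": "M1",
    "gene0002": "M1",
    "gene0003": "unassigned",
    "gene0004": "unassigned",
    "gene0005": "unassigned",
    "gene0006": "unassigned"
  },
  "triples": [
    {
      "metabolite": "met002",
      "gene_id": "gene0003",
      "variant_id": "chr01_000046208"
    }
  ]
}
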