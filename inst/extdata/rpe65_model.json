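{
  "gene_label": "RPE65",
  "coordinate_system": "CDS (c.), 1-based, closed intervals",
  "exons": [
    {
      "exon": 1,
      "c_start": 1,
      "c_end": 80,
      "inferred": true
    },
    {
      "exon": 2,
      "c_start": 81,
      "c_end": 165,
      "inferred": true
    },
    {
      "exon": 3,
      "c_start": 166,
      "c_end": 245,
      "inferred": true
    },
    {
      "exon": 4,
      "c_start": 246,
      "c_end": 353,
      "inferred": false
    },
    {
      "exon": 5,
      "c_start": 354,
      "c_end": 495,
      "inferred": false
    },
    {
      "exon": 6,
      "c_start": 496,
      "c_end": 643,
      "inferred": false
    },
    {
      "exon": 7,
      "c_start": 644,
      "c_end": 725,
      "inferred": false
    },
    {
      "exon": 8,
      "c_start": 726,
      "c_end": 858,
      "inferred": false
    },
    {
      "exon": 9,
      "c_start": 859,
      "c_end": 998,
      "inferred": false
    },
    {
      "exon": 10,
      "c_start": 999,
      "c_end": 1128,
      "inferred": false
    },
    {
      "exon": 11,
      "c_start": 1129,
      "c_end": 1243,
      "inferred": false
    },
    {
      "exon": 12,
      "c_start": 1244,
      "c_end": 1338,
      "inferred": false
    },
    {
      "exon": 13,
      "c_start": 1339,
      "c_end": 1450,
      "inferred": false
    },
    {
      "exon": 14,
      "c_start": 1451,
      "c_end": 1602,
      "inferred": true
    }
  ],
  "cds_length": 1602,
  "constructs": [
    {
      "name": "WT-1",
      "first_exon": 1,
      "last_exon": 5,
      "flank_5_len": 150,
      "flank_3_len": 130,
      "baseline": []
    },
    {
      "name": "WT-2",
      "first_exon": 3,
      "last_exon": 6,
      "flank_5_len": 150,
      "flank_3_len": 130,
      "baseline": []
    },
    {
      "name": "WT-3",
      "first_exon": 6,
      "last_exon": 10,
      "flank_5_len": 150,
      "flank_3_len": 130,
      "baseline": [
        {
          "events": "exon_skip:7",
          "fraction": 39
        }
      ]
    },
    {
      "name": "WT-4",
      "first_exon": 11,
      "last_exon": 13,
      "flank_5_len": 150,
      "flank_3_len": 130,
      "baseline": [
        {
          "events": "exon_skip:12",
          "fraction": 17
        },
        {
          "events": "pseudoexon:1129-293:1129-218",
          "fraction": 6
        }
      ]
    }
  ]
}
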