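<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic miniature metabolite database in HMDB-style XML layout.
     Monoisotopic masses are real literature values; the set is a small
     hand-picked fixture, not an HMDB excerpt. -->
<hmdb>
  <metabolite>
    <accession>HMDB0000122</accession>
    <name>D-Glucose</name>
    <chemical_formula>C6H12O6</chemical_formula>
    <monisotopic_molecular_weight>180.063388</monisotopic_molecular_weight>
  </metabolite>
  <metabolite>
    <accession>HMDB0000161</accession>
    <name>L-Alanine</name>
    <chemical_formula>C3H7NO2</chemical_formula>
    <monisotopic_molecular_weight>89.047679</monisotopic_molecular_weight>
  </metabolite>
  <metabolite>
    <accession>HMDB0000517</accession>
    <name>L-Arginine</name>
    <chemical_formula>C6H14N4O2</chemical_formula>
    <monisotopic_molecular_weight>174.111676</monisotopic_molecular_weight>
  </metabolite>
  <metabolite>
    <accession>HMDB0000251</accession>
    <name>Taurine</name>
    <chemical_formula>C2H7NO3S</chemical_formula>
    <monisotopic_molecular_weight>125.014664</monisotopic_molecular_weight>
  </metabolite>
  <metabolite>
    <accession>HMDB0000062</accession>
    <name>L-Carnitine</name>
    <chemical_formula>C7H15NO3</chemical_formula>
    <monisotopic_molecular_weight>161.105193</monisotopic_molecular_weight>
  </metabolite>
  <metabolite>
    <accession>HMDB0000687</accession>
    <name>L-Leucine</name>
    <chemical_formula>C6H13NO2</chemical_formula>
    <monisotopic_molecular_weight>131.094629</monisotopic_molecular_weight>
  </metabolite>
  <metabolite>
    <accession>HMDB0003070</accession>
    <name>Placeholder without mass</name>
    <chemical_formula>unknown</chemical_formula>
    <monisotopic_molecular_weight></monisotopic_molecular_weight>
  </metabolite>
</hmdb>
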