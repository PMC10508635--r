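"""Batch compound standardization and Morgan fingerprints via RDKit.

Invoked by the R package as a subprocess:

    python compound_tools.py standardize IN.csv OUT.csv
    python compound_tools.py fps IN.csv OUT.csv [--bits 1024 --radius 2]

standardize: IN.csv has columns compound_id, smiles. OUT.csv gains
canonical_smiles, inchikey, mw, passed_filters, rejection_reason.
Pipeline per record: parse -> largest organic fragment (salt strip) ->
canonical tautomer -> InChIKey -> molecular weight filter [180, 700].

fps: IN.csv has columns inchikey, canonical_smiles; OUT.csv has inchikey
and a 0/1 bitstring column of the hashed Morgan fingerprint (chirality
ignored).
"""
import csv
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Descriptors, rdFingerprintGenerator
from rdkit.Chem.MolStandardize import rdMolStandardize

RDLogger.DisableLog("rdApp.*")


def standardize(path_in, path_out):
    chooser = rdMolStandardize.LargestFragmentChooser()
    tautomerizer = rdMolStandardize.TautomerEnumerator()
    with open(path_in, newline="") as fin, open(path_out, "w", newline="") as fout:
        reader = csv.DictReader(fin)
        writer = csv.writer(fout)
        writer.writerow(["compound_id", "input_smiles", "canonical_smiles",
                         "inchikey", "mw", "passed_filters", "rejection_reason"])
        for row in reader:
            cid, smi = row["compound_id"], row["smiles"]
            canonical, inchikey, mw, passed, reason = "", "", "", "false", ""
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                reason = "parse_error"
            else:
                mol = chooser.choose(mol)
                try:
                    mol = tautomerizer.Canonicalize(mol)
                except Exception:
                    pass  # keep the un-canonicalized fragment
                canonical = Chem.MolToSmiles(mol)
                try:
                    inchikey = Chem.MolToInchiKey(mol)
                except Exception:
                    inchikey = ""
                w = Descriptors.MolWt(mol)
                mw = "%.4f" % w
                if not inchikey:
                    reason = "inchikey_error"
                elif w < 180.0:
                    reason = "mw_below_180"
                elif w > 700.0:
                    reason = "mw_above_700"
                else:
                    passed = "true"
            writer.writerow([cid, smi, canonical, inchikey, mw, passed, reason])


def fps(path_in, path_out, bits=1024, radius=2):
    gen = rdFingerprintGenerator.GetMorganGenerator(radius=radius, fpSize=bits,
                                                    includeChirality=False)
    with open(path_in, newline="") as fin, open(path_out, "w", newline="") as fout:
        reader = csv.DictReader(fin)
        writer = csv.writer(fout)
        writer.writerow(["inchikey", "bits"])
        for row in reader:
            mol = Chem.MolFromSmiles(row["canonical_smiles"])
            if mol is None:
                raise SystemExit("unparseable canonical SMILES for %s"
                                 % row["inchikey"])
            writer.writerow([row["inchikey"],
                             gen.GetFingerprint(mol).ToBitString()])


def main(argv):
    if len(argv) < 4:
        raise SystemExit(__doc__)
    mode, path_in, path_out = argv[1], argv[2], argv[3]
    opts = dict(zip(argv[4::2], argv[5::2]))
    if mode == "standardize":
        standardize(path_in, path_out)
    elif mode == "fps":
        fps(path_in, path_out, bits=int(opts.get("--bits", 1024)),
            radius=int(opts.get("--radius", 2)))
    else:
        raise SystemExit("unknown mode: " + mode)


if __name__ == "__main__":
    main(sys.argv)
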