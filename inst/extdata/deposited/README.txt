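Place locally downloaded coordinate models here to enable the
accession-based checks (they are far too large to ship with the
package sources and are not fetched automatically):

  6ZVR.pdb   Vipp1 C11 ring (55 chains)
  6ZW4.pdb   Vipp1 C14 ring (84 chains)
  4WHE.pdb   PspA partial structure

e.g. from https://files.rcsb.org/download/6ZVR.pdb
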