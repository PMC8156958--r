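# Reference site catalog for human 15LOX-2 (chain A, 4NRE numbering).
# E1/E3: surface entrances; S1/S2: channel binding sites; CAT: catalytic
# iron coordination shell; CLUSTER1-3: hydrophobic arrest clusters along
# the channels; WIDE: the wide-entrance tunnel (no occupancy claims
# attach to it). S0, the first-recognition site, is only ever described
# as transient occupancy of E1 and is mapped onto the E1 residue set with
# role "binding" -- a working definition, flagged as such.
sites:
  E1:
    role: entrance
    residues: [A:154:TYR, A:155:ASN, A:157:GLY, A:158:TRP, A:421:ILE,
               A:435:ILE, A:438:PHE, A:439:SER]
  E3:
    role: entrance
    residues: [A:573:SER, A:595:PRO, A:599:ALA, A:430:SER, A:603:VAL]
  S0:
    role: binding
    residues: [A:154:TYR, A:155:ASN, A:157:GLY, A:158:TRP, A:421:ILE,
               A:435:ILE, A:438:PHE, A:439:SER]
  S1:
    role: binding
    residues: [A:413:ASN, A:416:ALA, A:417:ARG, A:374:LEU, A:379:LEU]
  S2:
    role: binding
    residues: [A:433:ILE, A:431:THR, A:427:VAL, A:365:PHE, A:369:GLU]
  CAT:
    role: catalytic
    residues: [A:373:HIS, A:378:HIS, A:553:HIS, A:676:ILE]
  CLUSTER1:
    role: cluster
    residues: [A:216:ILE, A:604:ILE, A:561:PHE, A:564:CYS, A:565:ALA]
  CLUSTER2:
    role: cluster
    residues: [A:607:LEU, A:610:LEU, A:420:LEU, A:426:VAL, A:427:VAL]
  CLUSTER3:
    role: cluster
    residues: [A:246:LEU, A:364:GLU, A:365:PHE, A:368:HIS, A:369:GLU,
               A:570:LEU]
  WIDE:
    role: cluster
    residues: [A:610:LEU, A:560:GLN, A:613:GLU, A:557:SER, A:373:HIS,
               A:553:HIS, A:676:ILE]
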