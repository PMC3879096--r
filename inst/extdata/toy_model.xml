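<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy_branch" fbc:strict="true">
    <listOfParameters>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="lb_free" value="-1000" constant="true"/>
      <parameter id="ub_free" value="1000" constant="true"/>
      <parameter id="ub_glc" value="10" constant="true"/>
    </listOfParameters>
    <listOfSpecies>
      <species id="A" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
      <species id="B" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
      <species id="C" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
      <species id="A_ext" compartment="e" boundaryCondition="true" hasOnlySubstanceUnits="false" constant="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="R_upt" reversible="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_glc">
        <listOfReactants>
          <speciesReference species="A_ext" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_ab" reversible="true" fbc:lowerFluxBound="lb_free" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_ac2" reversible="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="C" stoichiometry="2" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_exb" reversible="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="R_exc" reversible="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="C" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
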