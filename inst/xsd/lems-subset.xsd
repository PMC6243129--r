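<?xml version="1.0" encoding="UTF-8"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema"
           elementFormDefault="unqualified">

  <!-- Implemented LEMS subset: flat ComponentTypes (no Structure /
       ForEach / KineticScheme), quantity-string parameter bindings on
       Component attributes, and a ModelAssembly link block. -->

  <xs:element name="Lems">
    <xs:complexType>
      <xs:choice minOccurs="0" maxOccurs="unbounded">
        <xs:element name="Dimension">
          <xs:complexType>
            <xs:attribute name="name" type="xs:string" use="required"/>
            <xs:attribute name="m" type="xs:integer"/>
            <xs:attribute name="l" type="xs:integer"/>
            <xs:attribute name="t" type="xs:integer"/>
            <xs:attribute name="i" type="xs:integer"/>
            <xs:attribute name="k" type="xs:integer"/>
            <xs:attribute name="n" type="xs:integer"/>
            <xs:attribute name="j" type="xs:integer"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="Unit">
          <xs:complexType>
            <xs:attribute name="symbol" type="xs:string" use="required"/>
            <xs:attribute name="dimension" type="xs:string" use="required"/>
            <xs:attribute name="power" type="xs:integer" use="required"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="ComponentType" type="componentTypeType"/>
        <xs:element name="Component" type="componentInstanceType"/>
        <xs:element name="ModelAssembly" type="modelAssemblyType"/>
      </xs:choice>
    </xs:complexType>
  </xs:element>

  <xs:complexType name="componentTypeType">
    <xs:choice minOccurs="0" maxOccurs="unbounded">
      <xs:element name="Parameter" type="namedDimensionedType"/>
      <xs:element name="Requirement" type="namedDimensionedType"/>
      <xs:element name="Exposure">
        <xs:complexType>
          <xs:attribute name="name" type="xs:string" use="required"/>
        </xs:complexType>
      </xs:element>
      <xs:element name="EventPort">
        <xs:complexType>
          <xs:attribute name="name" type="xs:string" use="required"/>
          <xs:attribute name="direction" use="required">
            <xs:simpleType>
              <xs:restriction base="xs:string">
                <xs:enumeration value="in"/>
                <xs:enumeration value="out"/>
              </xs:restriction>
            </xs:simpleType>
          </xs:attribute>
        </xs:complexType>
      </xs:element>
      <xs:element name="Dynamics" type="dynamicsType"/>
    </xs:choice>
    <xs:attribute name="name" type="xs:string" use="required"/>
  </xs:complexType>

  <xs:complexType name="namedDimensionedType">
    <xs:attribute name="name" type="xs:string" use="required"/>
    <xs:attribute name="dimension" type="xs:string" use="required"/>
  </xs:complexType>

  <xs:complexType name="dynamicsType">
    <xs:choice minOccurs="0" maxOccurs="unbounded">
      <xs:element name="StateVariable" type="namedDimensionedType"/>
      <xs:element name="DerivedVariable">
        <xs:complexType>
          <xs:attribute name="name" type="xs:string" use="required"/>
          <xs:attribute name="value" type="xs:string" use="required"/>
        </xs:complexType>
      </xs:element>
      <xs:element name="TimeDerivative">
        <xs:complexType>
          <xs:attribute name="variable" type="xs:string" use="required"/>
          <xs:attribute name="value" type="xs:string" use="required"/>
        </xs:complexType>
      </xs:element>
      <xs:element name="OnStart">
        <xs:complexType>
          <xs:sequence>
            <xs:element name="StateAssignment" type="stateAssignmentType"
                        minOccurs="0" maxOccurs="unbounded"/>
          </xs:sequence>
        </xs:complexType>
      </xs:element>
      <xs:element name="OnCondition">
        <xs:complexType>
          <xs:sequence>
            <xs:element name="StateAssignment" type="stateAssignmentType"
                        minOccurs="0" maxOccurs="unbounded"/>
            <xs:element name="EventOut" minOccurs="0">
              <xs:complexType>
                <xs:attribute name="port" type="xs:string" use="required"/>
              </xs:complexType>
            </xs:element>
          </xs:sequence>
          <xs:attribute name="test" type="xs:string" use="required"/>
        </xs:complexType>
      </xs:element>
      <xs:element name="OnEvent">
        <xs:complexType>
          <xs:sequence>
            <xs:element name="StateAssignment" type="stateAssignmentType"
                        minOccurs="0" maxOccurs="unbounded"/>
          </xs:sequence>
          <xs:attribute name="port" type="xs:string" use="required"/>
        </xs:complexType>
      </xs:element>
    </xs:choice>
  </xs:complexType>

  <xs:complexType name="stateAssignmentType">
    <xs:attribute name="variable" type="xs:string" use="required"/>
    <xs:attribute name="value" type="xs:string" use="required"/>
  </xs:complexType>

  <xs:complexType name="componentInstanceType">
    <xs:attribute name="id" type="xs:string" use="required"/>
    <xs:attribute name="type" type="xs:string" use="required"/>
    <xs:anyAttribute processContents="skip"/>
  </xs:complexType>

  <xs:complexType name="modelAssemblyType">
    <xs:choice minOccurs="0" maxOccurs="unbounded">
      <xs:element name="VariableLink" type="linkType"/>
      <xs:element name="EventLink" type="linkType"/>
    </xs:choice>
    <xs:attribute name="root" type="xs:string"/>
  </xs:complexType>

  <xs:complexType name="linkType">
    <xs:attribute name="from" type="xs:string" use="required"/>
    <xs:attribute name="to" type="xs:string" use="required"/>
  </xs:complexType>

</xs:schema>
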